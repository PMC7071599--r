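#' Tissue-block cluster design for expression simulation
#'
#' Builds the "stated world" used throughout the package's tests: clusters of
#' co-expressed transcripts, each highly expressed (at `fold` over basal) in
#' a block of tissues and basal elsewhere, mirroring the block structure of a
#' tissue-atlas heatmap. Tissues are split across clusters as evenly as
#' possible; `n_null` extra transcripts form a flat "cluster 0" with no
#' tissue specificity.
#'
#' @param n_clusters number of co-expression clusters.
#' @param n_tissues number of tissues (default 28).
#' @param transcripts_per_cluster transcripts in each cluster.
#' @param fold high/basal expression ratio (default 8).
#' @param n_null extra non-specific transcripts (cluster label 0).
#' @param tissue_names optional tissue codes; defaults to `T01..Tnn`.
#' @return list of per-cluster specs (`cluster`, `tissues`, `n`, `fold`)
#'   with class `cluster_design`.
#' @export
cluster_design <- function(n_clusters = 10L,
                           n_tissues = 28L,
                           transcripts_per_cluster = 50L,
                           fold = 8,
                           n_null = 0L,
                           tissue_names = NULL) {
  if (is.null(tissue_names)) tissue_names <- sprintf("T%02d", seq_len(n_tissues))
  stopifnot(length(tissue_names) == n_tissues, n_clusters >= 1)
  groups <- split(tissue_names,
                  rep(seq_len(n_clusters), length.out = n_tissues))
  design <- lapply(seq_len(n_clusters), function(k) {
    list(cluster = k, tissues = groups[[k]],
         n = as.integer(transcripts_per_cluster), fold = fold)
  })
  if (n_null > 0) {
    design <- c(design, list(list(cluster = 0L, tissues = character(0),
                                  n = as.integer(n_null), fold = 1)))
  }
  structure(design, class = "cluster_design", tissues = tissue_names)
}

#' Simulate per-tissue expression with co-expressed blocks
#'
#' Each transcript's mean abundance is `basal` in every tissue and
#' `basal * fold` in the tissues where its cluster is high. Replicates within
#' a tissue differ only by multiplicative lognormal noise with log-scale
#' standard deviation `sigma` (`sigma = 0` gives identical replicates).
#'
#' @param design a [cluster_design()] (or compatible list of specs).
#' @param reps_per_tissue biological replicates per tissue (default 8, the
#'   usual multiplex batch size).
#' @param basal basal mean abundance (default 10).
#' @param sigma lognormal sdlog of replicate noise (default 0.3).
#' @param seed integer seed.
#' @param transcript_ids optional ids; must match the design's total.
#' @return list with `expression` (transcripts x samples matrix),
#'   `cluster_of` (named integer vector), `tissue_of` (named character vector
#'   keyed by sample id), `tissues`.
#' @export
simulate_expression <- function(design,
                                reps_per_tissue = 8L,
                                basal = 10,
                                sigma = 0.3,
                                seed = NULL,
                                transcript_ids = NULL) {
  tissues <- attr(design, "tissues") %||%
    sort(unique(unlist(lapply(design, `[[`, "tissues"))))
  if (reps_per_tissue < 2)
    warning("fewer than 2 replicates per tissue: downstream differential ",
            "expression needs replication")
  if (!is.null(seed)) set.seed(seed)
  n_tx <- sum(vapply(design, `[[`, integer(1), "n"))
  if (is.null(transcript_ids)) transcript_ids <- sprintf("TX%05d", seq_len(n_tx))
  stopifnot(length(transcript_ids) == n_tx)

  sample_ids <- as.vector(vapply(tissues, function(tt)
    sprintf("%s_r%d", tt, seq_len(reps_per_tissue)),
    character(reps_per_tissue)))
  tissue_of <- rep(tissues, each = reps_per_tissue)
  names(tissue_of) <- sample_ids

  cluster_of <- integer(0)
  mean_mat <- matrix(basal, nrow = n_tx, ncol = length(tissues),
                     dimnames = list(transcript_ids, tissues))
  row <- 1L
  for (spec in design) {
    idx <- seq(row, length.out = spec$n)
    cluster_of <- c(cluster_of, rep(spec$cluster, spec$n))
    if (length(spec$tissues))
      mean_mat[idx, spec$tissues] <- basal * spec$fold
    row <- row + spec$n
  }
  names(cluster_of) <- transcript_ids

  expr <- mean_mat[, tissue_of, drop = FALSE]
  colnames(expr) <- sample_ids
  if (sigma > 0) {
    noise <- matrix(stats::rlnorm(length(expr), meanlog = 0, sdlog = sigma),
                    nrow = n_tx)
    expr <- expr * noise
  }
  list(expression = expr, cluster_of = cluster_of,
       tissue_of = tissue_of, tissues = tissues)
}

#' Build a multiplex sample sheet
#'
#' One row per sample with its tissue code and a unique sample barcode of
#' `barcode_len` nt, as used to demultiplex one sequencing run.
#'
#' @param sample_ids sample identifiers.
#' @param tissues tissue code per sample (recycled if length 1).
#' @param layout a [library_layout()] (supplies `barcode_len`).
#' @param seed integer seed for barcode generation.
#' @return data.frame with columns `sample_id`, `tissue`, `barcode`.
#' @export
make_sample_sheet <- function(sample_ids, tissues,
                              layout = library_layout(), seed = NULL) {
  n <- length(sample_ids)
  tissues <- rep_len(tissues, n)
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (4^layout$barcode_len < n)
    stop("barcode space too small for ", n, " samples")
  if (!is.null(seed)) set.seed(seed)
  barcodes <- character(0)
  while (length(barcodes) < n) {
    barcodes <- unique(c(barcodes,
                         random_dna(n - length(barcodes) + 4L,
                                    layout$barcode_len, gc = 0.5)))
  }
  data.frame(sample_id = sample_ids, tissue = tissues,
             barcode = barcodes[seq_len(n)], stringsAsFactors = FALSE)
}

#' Read / write a sample sheet TSV
#' @param path TSV path with columns `sample_id`, `tissue`, `barcode`.
#' @param sheet a sample-sheet data.frame.
#' @return `read_sample_sheet` returns the data.frame; `write_sample_sheet`
#'   returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("sample_id", "tissue", "barcode")
  if (!all(needed %in% names(df)))
    stop("sample sheet must have columns: ", paste(needed, collapse = ", "))
  df
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_sample_sheet <- function(sheet, layout) {
  needed <- c("sample_id", "tissue", "barcode")
  if (!all(needed %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(sheet$barcode))
    stop("barcode collision in sample sheet: ",
         paste(unique(sheet$barcode[duplicated(sheet$barcode)]), collapse = ", "))
  if (any(nchar(sheet$barcode) != layout$barcode_len))
    stop("all barcodes must have length ", layout$barcode_len)
  invisible(sheet)
}
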