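#' Read quality filter
#'
#' A base is "poor" when its Phred-implied accuracy, `1 - 10^(-Q/10)`, is
#' below `poor_accuracy_threshold`; a read fails when the fraction of poor
#' bases strictly exceeds `max_poor_fraction` (exactly 20% still passes).
#' Empty reads fail with reason `"empty"`.
#'
#' @param qualities character vector of Phred+33 quality strings, one per
#'   read.
#' @param poor_accuracy_threshold accuracy below which a base is poor
#'   (default 0.5, i.e. Phred < ~3).
#' @param max_poor_fraction maximum tolerated poor-base fraction (default
#'   0.20, strict inequality).
#' @return logical vector (`TRUE` = pass) with attribute `reason`
#'   (`"pass"`, `"poor_quality"`, or `"empty"`).
#' @examples
#' quality_filter(strrep("D", 50))            # all Q35: pass
#' quality_filter(paste0(strrep("!", 11), strrep("D", 39)))  # 22% poor: fail
#' @export
quality_filter <- function(qualities,
                           poor_accuracy_threshold = 0.5,
                           max_poor_fraction = 0.20) {
  poor_frac <- vapply(qualities, function(q) {
    if (!nzchar(q)) return(NA_real_)
    phred <- utf8ToInt(q) - 33L
    acc <- 1 - 10^(-phred / 10)
    mean(acc < poor_accuracy_threshold)
  }, numeric(1), USE.NAMES = FALSE)
  empty <- is.na(poor_frac)
  pass <- !empty & poor_frac <= max_poor_fraction
  reason <- ifelse(empty, "empty",
                   ifelse(pass, "pass", "poor_quality"))
  structure(pass, reason = reason)
}

#' Demultiplex reads by barcode prefix
#'
#' Compares the first `barcode_len` bases of each read to every sample
#' barcode. With `max_mismatch = 0` only exact prefix matches assign; with a
#' tolerance, the unique best barcode within `max_mismatch` wins and ties
#' leave the read unassigned. Unassigned is a value (`NA`), not an error.
#'
#' @param sequences character vector of read sequences.
#' @param sample_sheet data.frame with `sample_id` and `barcode` (equal
#'   lengths).
#' @param max_mismatch maximum Hamming distance (default 0).
#' @return character vector of sample ids, `NA` where unassigned.
#' @export
demultiplex <- function(sequences, sample_sheet, max_mismatch = 0L) {
  barcodes <- sample_sheet$barcode
  if (length(unique(nchar(barcodes))) != 1)
    stop("barcodes must all have the same length")
  bl <- nchar(barcodes[1])
  prefix <- toupper(substr(sequences, 1L, bl))
  if (max_mismatch == 0L) {
    idx <- match(prefix, toupper(barcodes))
    return(sample_sheet$sample_id[idx])
  }
  bc_mat <- do.call(rbind, strsplit(toupper(barcodes), "", fixed = TRUE))
  out <- rep(NA_character_, length(sequences))
  short <- nchar(prefix) < bl
  pf_mat <- do.call(rbind, strsplit(prefix[!short], "", fixed = TRUE))
  if (length(pf_mat)) {
    d <- matrix(0L, nrow(pf_mat), nrow(bc_mat))
    for (b in seq_len(nrow(bc_mat))) {
      d[, b] <- rowSums(pf_mat != matrix(bc_mat[b, ], nrow(pf_mat), bl,
                                         byrow = TRUE))
    }
    best <- apply(d, 1, min)
    hit <- best <= max_mismatch &
      rowSums(d == best) == 1L          # unique best, ties unassigned
    pick <- max.col(-d, ties.method = "first")
    out[!short][hit] <- sample_sheet$sample_id[pick[hit]]
  }
  out
}

#' Extract tags from demultiplexed reads
#'
#' Skips the barcode, discards the next `degenerate_len` bases (the "digital
#' removal" of the two random overhang bases), requires an exact anchor
#' match, and returns the following `tag_len` bases uppercased. Failures are
#' reported per read: `"truncated"` (read shorter than the layout minimum)
#' or `"no_anchor"`.
#'
#' @param sequences character vector of read sequences.
#' @param layout a [library_layout()].
#' @return character vector of tags, `NA` on failure, with attribute
#'   `reason` (`"ok"`, `"truncated"`, `"no_anchor"`).
#' @export
extract_tag <- function(sequences, layout = library_layout()) {
  validate_layout(layout)
  sequences <- toupper(sequences)
  anchor_len <- nchar(layout$anchor)
  a_start <- layout$barcode_len + layout$degenerate_len + 1L
  t_start <- a_start + anchor_len
  min_len <- layout_min_read(layout)

  truncated <- nchar(sequences) < min_len
  anchor_ok <- !truncated &
    substr(sequences, a_start, t_start - 1L) == layout$anchor
  tags <- rep(NA_character_, length(sequences))
  tags[anchor_ok] <- substr(sequences[anchor_ok], t_start,
                            t_start + layout$tag_len - 1L)
  reason <- ifelse(truncated, "truncated",
                   ifelse(anchor_ok, "ok", "no_anchor"))
  structure(tags, reason = reason)
}

#' Run the full extraction pipeline on a multiplexed read set
#'
#' Quality filter, then demultiplex, then tag extraction, with exact
#' per-sample accounting: `reads_total` equals
#' `reads_failed_quality + reads_no_barcode + reads_no_anchor + tags_emitted`
#' in every sample (reads failing quality or demultiplexing are counted
#' run-wide and attributed to no sample; the `__run__` stats row carries
#' them).
#'
#' @param reads data.frame with `sequence` and `quality` (e.g. from
#'   [read_fastq()] or [simulate_reads()]).
#' @param sample_sheet data.frame with `sample_id`, `tissue`, `barcode`.
#' @param layout a [library_layout()].
#' @param max_mismatch barcode mismatch tolerance (default 0).
#' @param poor_accuracy_threshold,max_poor_fraction see [quality_filter()].
#' @return list with `tags` (named list: sample id -> character vector of
#'   tags) and `stats` (data.frame with one row per sample plus a `__run__`
#'   row aggregating the whole run: `reads_total`, `reads_failed_quality`,
#'   `reads_no_barcode`, `reads_no_anchor`, `tags_emitted`).
#' @export
extract_tags <- function(reads, sample_sheet, layout = library_layout(),
                         max_mismatch = 0L,
                         poor_accuracy_threshold = 0.5,
                         max_poor_fraction = 0.20) {
  validate_layout(layout)
  validate_sample_sheet(sample_sheet, layout)
  n <- nrow(reads)
  pass_q <- quality_filter(reads$quality, poor_accuracy_threshold,
                           max_poor_fraction)
  assigned <- rep(NA_character_, n)
  assigned[pass_q] <- demultiplex(reads$sequence[pass_q], sample_sheet,
                                  max_mismatch)
  tag <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  idx <- which(pass_q & !is.na(assigned))
  if (length(idx)) {
    ext <- extract_tag(reads$sequence[idx], layout)
    tag[idx] <- as.vector(ext)
    reason[idx] <- attr(ext, "reason")
  }

  samples <- sample_sheet$sample_id
  tags <- lapply(samples, function(s) {
    v <- tag[!is.na(assigned) & assigned == s]
    v[!is.na(v)]
  })
  names(tags) <- samples

  per_sample <- function(s) {
    sel <- !is.na(assigned) & assigned == s
    c(reads_total = sum(sel),
      reads_failed_quality = 0L,
      reads_no_barcode = 0L,
      reads_no_anchor = sum(sel & reason %in% c("no_anchor", "truncated")),
      tags_emitted = sum(sel & !is.na(tag)))
  }
  stats <- t(vapply(samples, per_sample, integer(5)))
  run <- c(reads_total = n,
           reads_failed_quality = sum(!pass_q),
           reads_no_barcode = sum(pass_q & is.na(assigned)),
           reads_no_anchor = sum(reason %in% c("no_anchor", "truncated"),
                                 na.rm = TRUE),
           tags_emitted = sum(!is.na(tag)))
  stats <- rbind(stats, `__run__` = run)
  stats <- data.frame(sample_id = rownames(stats), stats,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(tags = tags, stats = stats)
}
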