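#' Position weight matrix for motif scanning
#'
#' @param id motif identifier (e.g. `"MA0002.2"`).
#' @param name transcription-factor name.
#' @param counts width x 4 matrix of base counts (columns A, C, G, T) or
#'   probabilities; `pseudocount` is added to every cell before row-wise
#'   normalization.
#' @param pseudocount per-cell pseudocount (default 0.375).
#' @return object of class `MotifPWM`: list with `id`, `name`, `probs`
#'   (width x 4, rows summing to 1), `pseudocount`.
#' @export
motif_pwm <- function(id, name, counts, pseudocount = 0.375) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4)
    stop("motif ", id, ": matrix must have 4 columns (A, C, G, T)")
  if (any(counts < 0)) stop("motif ", id, ": negative counts")
  probs <- counts + pseudocount
  probs <- probs / rowSums(probs)
  colnames(probs) <- DNA_BASES
  rownames(probs) <- NULL
  structure(list(id = id, name = name, probs = probs,
                 pseudocount = pseudocount),
            class = "MotifPWM")
}

pwm_width <- function(pwm) nrow(pwm$probs)

#' @export
print.MotifPWM <- function(x, ...) {
  cat(sprintf("MotifPWM %s (%s), width %d\n", x$id, x$name, pwm_width(x)))
  invisible(x)
}

#' Read / write JASPAR flat-format PWM files
#'
#' Parses the JASPAR 2016+ flat format: a header line `>ID NAME` followed by
#' four base rows, either bracketed (`A [ 4 19 0 ]`) or bare numbers
#' (assumed A, C, G, T order). Counts are converted to probabilities after
#' adding `pseudocount` per cell. Ragged matrices raise an error naming the
#' motif.
#'
#' @param path file path.
#' @param pseudocount per-cell pseudocount (default 0.375).
#' @param pwms list of `MotifPWM` objects to write (their probability
#'   matrices are written; read back with `pseudocount = 0` to round-trip).
#' @return `read_jaspar` returns a named list of [motif_pwm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.375) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no JASPAR records found in ", path)
  bounds <- c(headers, length(lines) + 1L)
  pwms <- list()
  for (i in seq_along(headers)) {
    hdr <- sub("^>\\s*", "", lines[headers[i]])
    parts <- strsplit(hdr, "[ \t]+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else id
    body <- lines[seq(headers[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) != 4)
      stop("motif ", id, ": expected 4 matrix rows, found ", length(body))
    rows <- lapply(body, function(l) {
      l <- sub("^\\s*[ACGTacgt]\\s*", "", l)      # optional base label
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)  # optional brackets
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1 || any(is.na(unlist(rows))))
      stop("motif ", id, ": ragged or malformed matrix rows")
    counts <- t(do.call(rbind, rows))  # width x 4, A C G T
    pwms[[id]] <- motif_pwm(id, name, counts, pseudocount)
  }
  pwms
}

#' @rdname read_jaspar
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id, "\t", p$name), con)
    for (b in seq_len(4)) {
      writeLines(paste0(DNA_BASES[b], "  [ ",
                        paste(format(p$probs[, b], digits = 15),
                              collapse = " "),
                        " ]"), con)
    }
  }
  invisible(path)
}

# Per-position per-strand likelihood ratios of a single sequence.
# Positions containing N contribute a factor of 1 at that base.
scan_site_lrs <- function(seq, pwm, background) {
  w <- pwm_width(pwm)
  if (nchar(seq) < w)
    stop("sequence shorter than the motif width ", w)
  logw <- log(sweep(pwm$probs, 2, background[DNA_BASES], "/"))
  scan_one <- function(s_int) {
    np <- length(s_int) - w + 1L
    acc <- numeric(np)
    for (j in seq_len(w)) {
      v <- s_int[j:(j + np - 1L)]
      ok <- v > 0L
      add <- numeric(np)
      add[ok] <- logw[j, ][v[ok]]
      acc <- acc + add
    }
    acc
  }
  fwd <- scan_one(dna_to_int(seq))
  rev <- scan_one(dna_to_int(revcomp(seq)))
  exp(c(fwd, rev))
}

#' Likelihood-ratio score of one sequence for a PWM
#'
#' At every position on both strands the likelihood ratio
#' `prod_j pwm[j, base] / background[base]` is computed (N positions
#' contribute 1); `avg_lr` is the arithmetic mean over all sites of both
#' strands, the per-sequence quantity Clover-style scoring aggregates.
#'
#' @param seq one DNA string (length >= motif width).
#' @param pwm a [motif_pwm()].
#' @param background strictly positive base frequencies, named A, C, G, T.
#' @return list with `avg_lr` and `site_lrs` (all per-position per-strand
#'   likelihood ratios, forward positions first).
#' @export
sequence_score <- function(seq, pwm, background = uniform_background()) {
  check_background(background)
  lrs <- scan_site_lrs(toupper(seq), pwm, background)
  list(avg_lr = mean(lrs), site_lrs = lrs)
}

#' @rdname sequence_score
#' @export
uniform_background <- function() c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

check_background <- function(background) {
  if (!all(DNA_BASES %in% names(background)))
    stop("background must be named with A, C, G, T")
  if (any(background[DNA_BASES] <= 0))
    stop("background frequencies must be strictly positive")
  invisible(background)
}

#' Base frequencies of a sequence set
#' @param seqs character vector or DNAStringSet.
#' @return named frequencies over A, C, G, T (other letters ignored).
#' @export
base_frequencies <- function(seqs) {
  seqs <- as_dna_character(seqs)
  counts <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                        DNA_BASES)
  tot <- colSums(counts)
  tot / sum(tot)
}

# ln(avg_lr) per sequence, the additive building block of the set score.
seq_log_avg_lr <- function(seqs, pwm, background) {
  vapply(seqs, function(s) log(mean(scan_site_lrs(s, pwm, background))),
         numeric(1), USE.NAMES = FALSE)
}

#' Set-level raw over-representation score
#'
#' `raw_score = sum over sequences of ln(avg_lr)`: additive across
#' sequences, zero for a completely uninformative motif, and negative when
#' the motif is depleted relative to background.
#'
#' @param seqs foreground sequences (character vector or DNAStringSet, at
#'   least one).
#' @inheritParams sequence_score
#' @return scalar raw score.
#' @export
set_raw_score <- function(seqs, pwm, background = uniform_background()) {
  seqs <- as_dna_character(seqs)
  if (length(seqs) < 1) stop("need at least one sequence")
  check_background(background)
  sum(seq_log_avg_lr(seqs, pwm, background))
}

#' Randomization p-value for motif over-representation
#'
#' Compares the observed foreground raw score with scores of `n_rand`
#' random sequence sets, with the add-one estimator
#' `p = (1 + #{random >= observed}) / (1 + n_rand)` (so p is never 0 and
#' never below `1/(n_rand + 1)`). Two randomization controls are available:
#' `"draw_matched_background"` draws `|foreground|` sequences from the
#' GC-matched background pool without replacement per replicate;
#' `"shuffle_mononucleotide"` permutes the bases within each foreground
#' sequence.
#'
#' @param foreground foreground sequences.
#' @param pwm a [motif_pwm()].
#' @param background_pool background sequences (pool for the draw strategy).
#' @param n_rand number of randomizations (default 1000; must be >= 19 to
#'   resolve p <= 0.05).
#' @param strategy randomization control.
#' @param background base frequencies (default: estimated from the pool).
#' @param seed integer seed.
#' @return scalar p-value in `[1/(n_rand+1), 1]`.
#' @export
randomization_p <- function(foreground, pwm, background_pool,
                            n_rand = 1000L,
                            strategy = c("draw_matched_background",
                                         "shuffle_mononucleotide"),
                            background = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  if (n_rand < 19) stop("n_rand must be >= 19 to resolve p <= 0.05")
  foreground <- as_dna_character(foreground, "foreground")
  background_pool <- as_dna_character(background_pool, "background_pool")
  background <- background %||% base_frequencies(background_pool)
  check_background(background)
  nf <- length(foreground)
  if (strategy == "draw_matched_background" && length(background_pool) < nf)
    stop("background pool smaller than the foreground set")
  if (!is.null(seed)) set.seed(seed)
  obs <- set_raw_score(foreground, pwm, background)
  if (strategy == "draw_matched_background") {
    pool_scores <- seq_log_avg_lr(background_pool, pwm, background)
    rand <- vapply(seq_len(n_rand), function(r) {
      sum(pool_scores[sample.int(length(pool_scores), nf)])
    }, numeric(1))
  } else {
    rand <- vapply(seq_len(n_rand), function(r) {
      shuffled <- vapply(foreground, function(s) {
        paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
      set_raw_score(shuffled, pwm, background)
    }, numeric(1))
  }
  (1 + sum(rand >= obs)) / (1 + n_rand)
}

#' Count above-threshold binding sites
#'
#' `occurrence` is the total number of site likelihood ratios above
#' `lr_threshold` across all sequences and strands (overlapping sites count
#' independently); `gene_count` is the number of sequences with at least one
#' such site.
#'
#' @param seqs sequences to scan.
#' @param pwm a [motif_pwm()].
#' @param background base frequencies.
#' @param lr_threshold site-call threshold on the likelihood ratio (default
#'   `2^6`, i.e. 6 bits over background).
#' @return list with `occurrence` and `gene_count`.
#' @export
site_calls <- function(seqs, pwm, background = uniform_background(),
                       lr_threshold = 2^6) {
  if (lr_threshold <= 0) stop("lr_threshold must be positive")
  seqs <- as_dna_character(seqs)
  check_background(background)
  per_seq <- vapply(seqs, function(s)
    sum(scan_site_lrs(s, pwm, background) > lr_threshold),
    numeric(1), USE.NAMES = FALSE)
  list(occurrence = as.integer(sum(per_seq)),
       gene_count = as.integer(sum(per_seq > 0)))
}

#' Motif over-representation report across clusters
#'
#' For every (promoter cluster, motif) pair computes the site calls, raw
#' score, and randomization p-value against the background pool, then
#' adjusts p-values across motifs within each cluster (Benjamini-Hochberg)
#' and flags significance at `fdr <= alpha`. Rows are sorted by raw score
#' within each cluster; `top_n` limits the rows reported per cluster.
#'
#' @param clusters named list: cluster label -> promoter sequences.
#' @param motifs list of [motif_pwm()] objects (e.g. from [read_jaspar()]).
#' @param background_pool GC-matched background promoter sequences.
#' @param alpha FDR significance gate (default 0.05).
#' @param n_rand randomizations per test (default 1000).
#' @param strategy see [randomization_p()].
#' @param lr_threshold see [site_calls()].
#' @param top_n rows reported per cluster (default all).
#' @param seed integer seed.
#' @return data.frame of class `MotifReport` with columns `cluster`,
#'   `jaspar_id`, `tf_name`, `occurrence`, `gene_count`, `raw_score`, `p`,
#'   `fdr`, `significant`.
#' @export
enrichment_report <- function(clusters, motifs, background_pool,
                              alpha = 0.05, n_rand = 1000L,
                              strategy = "draw_matched_background",
                              lr_threshold = 2^6, top_n = Inf, seed = NULL) {
  stopifnot(is.list(clusters), !is.null(names(clusters)))
  background_pool <- as_dna_character(background_pool, "background_pool")
  background <- base_frequencies(background_pool)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (cl in names(clusters)) {
    seqs <- clusters[[cl]]
    if (length(seqs) == 0) {
      warning("cluster ", cl, " has no promoters; skipped")
      next
    }
    seqs <- as_dna_character(seqs)
    rows <- lapply(motifs, function(pwm) {
      calls <- site_calls(seqs, pwm, background, lr_threshold)
      data.frame(cluster = cl, jaspar_id = pwm$id, tf_name = pwm$name,
                 occurrence = calls$occurrence,
                 gene_count = calls$gene_count,
                 raw_score = set_raw_score(seqs, pwm, background),
                 p = randomization_p(seqs, pwm, background_pool,
                                     n_rand = n_rand, strategy = strategy,
                                     background = background,
                                     seed = sample.int(.Machine$integer.max,
                                                       1)),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$fdr <- bh_adjust(tab$p)
    tab$significant <- tab$fdr <= alpha
    tab <- tab[order(-tab$raw_score), , drop = FALSE]
    if (is.finite(top_n)) tab <- utils::head(tab, top_n)
    out[[cl]] <- tab
  }
  report <- do.call(rbind, out)
  if (is.null(report)) {
    report <- data.frame(cluster = character(0), jaspar_id = character(0),
                         tf_name = character(0), occurrence = integer(0),
                         gene_count = integer(0), raw_score = numeric(0),
                         p = numeric(0), fdr = numeric(0),
                         significant = logical(0))
  }
  rownames(report) <- NULL
  class(report) <- c("MotifReport", "data.frame")
  report
}
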