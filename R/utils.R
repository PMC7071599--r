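`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Generate random DNA sequences with a given GC content
#'
#' @param n number of sequences.
#' @param length sequence length(s), recycled to `n`.
#' @param gc target GC fraction, strictly between 0 and 1.
#' @return character vector of `n` uppercase DNA strings.
#' @keywords internal
random_dna <- function(n, length, gc = 0.5) {
  if (gc <= 0 || gc >= 1) stop("`gc` must lie strictly between 0 and 1")
  length <- rep_len(as.integer(length), n)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length[i], replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA (IUPAC letters allowed).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Encode DNA as integers 1..4 (A,C,G,T); anything else (N, gaps) -> 0L.
dna_to_int <- function(seq) {
  m <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
  m[is.na(m)] <- 0L
  m
}

# Coerce DNAStringSet / named character to a named character vector.
as_dna_character <- function(x, arg = "sequences") {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    stop("`", arg, "` must be a character vector or DNAStringSet")
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two labelings of the same items, corrected for chance.
#' Equals 1 for identical partitions (up to label permutation) and is ~0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Benjamini-Hochberg adjustment (thin wrapper kept for a single call site).
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
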