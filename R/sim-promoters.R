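#' Simulate promoter sets with planted motif sites
#'
#' Generates a foreground set of promoter-length sequences in which a binding
#' site sampled from `pwm` is planted at rate `plant_rate` (uniform position,
#' random strand), and an i.i.d. background set with matching GC content.
#' This mirrors the usual over-representation design: cluster promoters
#' versus GC-matched background promoters.
#'
#' @param n_fore,n_back number of foreground / background sequences.
#' @param length sequence length in nt (default 1000, i.e. 1 kb upstream of
#'   the TSS).
#' @param pwm a [motif_pwm()] to plant (its width must be < `length`).
#' @param plant_rate probability that a foreground sequence receives one
#'   planted site, in [0, 1].
#' @param gc GC fraction of the random background composition.
#' @param seed integer seed.
#' @param fore_fasta,back_fasta optional FASTA output paths.
#' @return list with `foreground`, `background` (named character vectors),
#'   and `planted` (named list: foreground id -> list(offset, strand); only
#'   ids that received a site).
#' @export
simulate_promoters <- function(n_fore, n_back, length = 1000L, pwm,
                               plant_rate = 1, gc = 0.5, seed = NULL,
                               fore_fasta = NULL, back_fasta = NULL) {
  if (plant_rate < 0 || plant_rate > 1) stop("plant_rate must lie in [0, 1]")
  w <- pwm_width(pwm)
  if (w >= length) stop("PWM width must be smaller than the promoter length")
  if (!is.null(seed)) set.seed(seed)

  fore <- random_dna(n_fore, length, gc)
  names(fore) <- sprintf("FG%04d", seq_len(n_fore))
  back <- random_dna(n_back, length, gc)
  names(back) <- sprintf("BG%04d", seq_len(n_back))

  planted <- list()
  for (i in seq_len(n_fore)) {
    if (stats::runif(1) > plant_rate) next
    site <- sample_pwm_site(pwm)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") site <- revcomp(site)
    offset <- sample.int(length - w + 1L, 1)
    substr(fore[i], offset, offset + w - 1L) <- site
    planted[[names(fore)[i]]] <- list(offset = offset, strand = strand)
  }
  if (!is.null(fore_fasta))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(fore), fore_fasta)
  if (!is.null(back_fasta))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(back), back_fasta)
  list(foreground = fore, background = back, planted = planted)
}

# Draw one site from the PWM's per-position base distributions.
sample_pwm_site <- function(pwm) {
  paste(apply(pwm$probs, 1, function(p) sample(DNA_BASES, 1, prob = p)),
        collapse = "")
}
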