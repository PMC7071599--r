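# Shared fixtures, all built in code under fixed seeds.

default_layout <- function() library_layout()

# Layout with a short read for compact hand-built reads in unit tests.
tiny_layout <- function() library_layout(barcode_len = 4L, read_len = 40L)

# A strong 8 bp motif (information content >> 10 bits with pc = 0.375).
strong_pwm <- function(id = "MA9999.1", name = "PLANTED") {
  # non-palindromic, non-self-overlapping consensus (CCAGATAA)
  consensus <- c("C", "C", "A", "G", "A", "T", "A", "A")
  counts <- matrix(0, nrow = 8, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(consensus)) counts[i, consensus[i]] <- 100
  motif_pwm(id, name, counts)
}

# Uninformative PWM: every base equiprobable at every position.
identity_pwm <- function(width = 6L) {
  motif_pwm("IDENT", "identity",
            matrix(1, nrow = width, ncol = 4), pseudocount = 0)
}

# Decoy PWMs sampled from random count matrices.
decoy_pwms <- function(n, width = 8L, seed = 100L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    counts <- matrix(stats::rmultinom(width, 100, rep(0.25, 4)),
                     ncol = 4, byrow = TRUE)
    motif_pwm(sprintf("DEC%03d", i), sprintf("decoy%d", i), counts)
  })
}

# Small end-to-end simulation reused by extract/quantify tests.
small_simulation <- function(n_transcripts = 60, n_tissues = 3,
                             reps = 2, depth = 1500, seed = 42,
                             error_rate = 0, low_quality_fraction = 0) {
  lay <- library_layout()
  tx <- simulate_transcriptome(n_transcripts, untaggable_frac = 0,
                               seed = seed)
  des <- cluster_design(n_clusters = n_tissues, n_tissues = n_tissues,
                        transcripts_per_cluster = n_transcripts %/% n_tissues,
                        n_null = n_transcripts %% n_tissues)
  ex <- simulate_expression(des, reps_per_tissue = reps, seed = seed + 1)
  sheet <- make_sample_sheet(colnames(ex$expression), ex$tissue_of, lay,
                             seed = seed + 2)
  sim <- simulate_reads(ex$expression, tx$tag_of, sheet, lay, depth = depth,
                        error_rate = error_rate,
                        low_quality_fraction = low_quality_fraction,
                        seed = seed + 3)
  list(layout = lay, tx = tx, ex = ex, sheet = sheet, sim = sim)
}
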