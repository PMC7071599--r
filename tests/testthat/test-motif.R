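test_that("JASPAR parsing handles brackets, labels, and pseudocounts", {
  p <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 TESTA",
    "A  [ 10 10 10 10 ]",
    "C  [ 10 10 10 10 ]",
    "G  [ 10 10 10 10 ]",
    "T  [ 10 10 10 10 ]",
    ">MA0002.1 TESTB",
    "10 0 0",
    "0 10 0",
    "0 0 10",
    "0 0 0"), p)
  pwms <- read_jaspar(p)
  expect_named(pwms, c("MA0001.1", "MA0002.1"))
  # equal counts -> all probabilities 0.25 at every position
  expect_equal(unname(pwms[["MA0001.1"]]$probs),
               matrix(0.25, 4, 4), tolerance = 1e-12)
  # pure counts with pc = 0 give probability-1 columns
  pwms0 <- read_jaspar(p, pseudocount = 0)
  expect_equal(unname(pwms0[["MA0002.1"]]$probs[, "A"]), c(1, 0, 0))
  # ragged matrix errors, naming the motif
  writeLines(c(">MA0003.1 BAD", "1 2 3", "1 2", "1 2 3", "1 2 3"), p)
  expect_error(read_jaspar(p), "MA0003.1")
})

test_that("write/read round-trips probabilities to 1e-9", {
  pwm <- strong_pwm()
  p <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(list(pwm), p)
  back <- read_jaspar(p, pseudocount = 0)[[1]]
  expect_equal(back$probs, pwm$probs, tolerance = 1e-9)
  expect_equal(back$id, pwm$id)
  expect_equal(back$name, pwm$name)
})

test_that("likelihood ratios match brute-force site enumeration", {
  # uniform motif on uniform background: every LR is exactly 1
  sc <- sequence_score("ACGTACGTAC", identity_pwm(4))
  expect_true(all(sc$site_lrs == 1))
  expect_identical(sc$avg_lr, 1)
  # hand-computed: width-1 A-only motif (pc = 0) on "AAAA":
  # forward LRs all 1/0.25 = 4; reverse strand scans "TTTT" -> all 0
  a_only <- motif_pwm("A1", "aonly", matrix(c(1, 0, 0, 0), 1),
                      pseudocount = 0)
  sc2 <- sequence_score("AAAA", a_only)
  expect_equal(sort(sc2$site_lrs), c(0, 0, 0, 0, 4, 4, 4, 4))
  expect_equal(sc2$avg_lr, 2)
  # N positions contribute a factor of 1
  sc3 <- sequence_score("N", a_only)
  expect_equal(sc3$site_lrs, c(1, 1))
  # strand symmetry: reverse-complementing the sequence preserves avg_lr
  pwm <- strong_pwm()
  set.seed(40)
  seq <- sagescape:::random_dna(1, 60, 0.5)
  expect_equal(sequence_score(seq, pwm)$avg_lr,
               sequence_score(sagescape:::revcomp(seq), pwm)$avg_lr,
               tolerance = 1e-12)
  expect_error(sequence_score("ACG", pwm), "shorter")
  # independent oracle: per-position product recomputed directly
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  seq2 <- "ACGTTG"
  w <- nrow(pwm$probs)  # 8 > 6: use a narrow pwm instead
  np <- motif_pwm("NP", "np", matrix(c(5, 1, 1, 1, 1, 5, 1, 1), 2,
                                     byrow = TRUE), pseudocount = 0)
  manual <- function(s) {
    chars <- strsplit(s, "")[[1]]
    sapply(1:(length(chars) - 1), function(i) {
      np$probs[1, chars[i]] / bg[chars[i]] *
        np$probs[2, chars[i + 1]] / bg[chars[i + 1]]
    })
  }
  got <- sequence_score(seq2, np, bg)
  expected <- c(manual(seq2), manual(sagescape:::revcomp(seq2)))
  expect_equal(sort(got$site_lrs), sort(unname(expected)), tolerance = 1e-12)
})

test_that("set raw score is additive, zero for uniform motifs, higher when planted", {
  seqs <- c("ACGTACGTACGT", "TTGACATGCCAA")
  expect_identical(set_raw_score(seqs, identity_pwm(4)), 0)
  one <- set_raw_score(seqs[1], strong_pwm())
  expect_equal(one, log(sequence_score(seqs[1], strong_pwm())$avg_lr))
  expect_equal(set_raw_score(seqs, strong_pwm()),
               sum(vapply(seqs, function(s)
                 log(sequence_score(s, strong_pwm())$avg_lr), numeric(1))))
  # planted foreground beats unplanted in paired seeded trials
  pwm <- strong_pwm()
  wins <- vapply(1:20, function(i) {
    pr <- simulate_promoters(8, 8, length = 150, pwm = pwm, plant_rate = 1,
                             seed = 100 + i)
    set_raw_score(pr$foreground, pwm) > set_raw_score(pr$background, pwm)
  }, logical(1))
  expect_true(all(wins))
})

test_that("randomization p-values are bounded, calibrated, and powered", {
  pwm <- strong_pwm()
  pr <- simulate_promoters(12, 80, length = 200, pwm = pwm, plant_rate = 1,
                           seed = 50)
  # strong planting vs unplanted pool reaches the add-one minimum
  p_min <- randomization_p(pr$foreground, pwm, pr$background, n_rand = 99,
                           seed = 51)
  expect_equal(p_min, 1 / 100)
  expect_gte(p_min, 1 / 100); expect_lte(p_min, 1)
  # null calibration: foreground drawn from the same pool
  null_ps <- vapply(1:25, function(i) {
    set.seed(200 + i)
    fg <- sample(pr$background, 10)
    randomization_p(fg, pwm, pr$background, n_rand = 39, seed = 300 + i)
  }, numeric(1))
  expect_gt(mean(null_ps), 0.3); expect_lt(mean(null_ps), 0.7)
  # shuffle strategy destroys a planted signal's advantage source
  p_shuf <- randomization_p(pr$foreground, pwm, pr$background, n_rand = 49,
                            strategy = "shuffle_mononucleotide", seed = 52)
  expect_lte(p_shuf, 0.05)
  expect_error(randomization_p(pr$foreground, pwm, pr$background,
                               n_rand = 10), "19")
  expect_error(randomization_p(pr$background, pwm, pr$foreground,
                               n_rand = 19), "smaller")
})

test_that("site calls count thresholded sites per sequence and in total", {
  pwm <- strong_pwm()
  consensus <- "CCAGATAA"
  none <- site_calls(strrep("T", 50), pwm)
  expect_equal(none$occurrence, 0L)
  expect_equal(none$gene_count, 0L)
  # one planted consensus site in each of 10 sequences
  set.seed(53)
  seqs <- vapply(1:10, function(i) {
    s <- strrep("T", 60)
    pos <- sample(1:(60 - 8 + 1), 1)
    substr(s, pos, pos + 7) <- consensus
    s
  }, character(1))
  calls <- site_calls(seqs, pwm)
  expect_equal(calls$occurrence, 10L)
  expect_equal(calls$gene_count, 10L)
  expect_gte(calls$occurrence, calls$gene_count)
})

test_that("the enrichment report ranks a planted motif first among decoys", {
  pwm <- strong_pwm()
  decoys <- decoy_pwms(8)
  pr <- simulate_promoters(20, 120, length = 300, pwm = pwm,
                           plant_rate = 0.8, seed = 54)
  rep <- enrichment_report(list(c1 = pr$foreground),
                           c(list(pwm), decoys), pr$background,
                           n_rand = 199, seed = 55)
  expect_s3_class(rep, "MotifReport")
  expect_equal(rep$jaspar_id[1], pwm$id)   # ranked first by raw score
  expect_lte(rep$fdr[rep$jaspar_id == pwm$id], 0.05)
  expect_true(all(c("cluster", "jaspar_id", "tf_name", "occurrence",
                    "gene_count", "raw_score", "fdr") %in% names(rep)))
  expect_true(all(rep$p >= 1 / 200 & rep$p <= 1))
  # alpha = 0: nothing significant
  rep0 <- enrichment_report(list(c1 = pr$foreground), list(pwm),
                            pr$background, alpha = 0, n_rand = 39, seed = 56)
  expect_false(any(rep0$significant))
  expect_warning(enrichment_report(list(empty = character(0)), list(pwm),
                                   pr$background, n_rand = 39, seed = 57),
                 "skipped")
})
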