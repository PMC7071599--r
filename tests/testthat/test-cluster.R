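planted_adjusted <- function(n_clusters = 10, per_cluster = 50,
                             n_tissues = 28, reps = 8, sigma = 0.2,
                             seed = 20) {
  des <- cluster_design(n_clusters = n_clusters, n_tissues = n_tissues,
                        transcripts_per_cluster = per_cluster, fold = 8)
  ex <- simulate_expression(des, reps_per_tissue = reps, sigma = sigma,
                            seed = seed)
  l2 <- log2_transform(expression_matrix(ex$expression, "raw"))
  list(adj = adjust_rows(l2), truth = ex$cluster_of)
}

test_that("row adjustment median-centers, unit-normalizes, and is idempotent", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("r1", NULL))
  adj <- adjust_rows(m)
  expect_equal(unname(adj[1, ]), c(-1, 0, 1) / sqrt(2), tolerance = 1e-9)
  set.seed(21)
  mr <- matrix(rnorm(200), 20, dimnames = list(paste0("r", 1:20), NULL))
  a1 <- adjust_rows(mr)
  expect_equal(unname(sqrt(rowSums(a1^2))), rep(1, 20), tolerance = 1e-9)
  expect_equal(unclass(adjust_rows(a1)), unclass(a1),
               ignore_attr = TRUE, tolerance = 1e-9)
  # constant rows are dropped with a warning
  mc <- rbind(mr, const = rep(5, 10))
  expect_warning(a2 <- adjust_rows(mc), "constant")
  expect_false("const" %in% rownames(a2))
})

test_that("Lloyd objective is non-increasing and K = 1 gives total centered SS", {
  set.seed(22)
  x <- matrix(rnorm(100 * 5), 100)
  fit <- sagescape:::lloyd_kmeans(x, x[sample(100, 4), ])
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  res1 <- kmeans_bf98(x, K = 1, S = 5, seed = 23, n_final_runs = 1)
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(res1$within_ss, sum(centered^2), tolerance = 1e-8)
  expect_error(kmeans_bf98(x, K = 101, S = 5), "exceeds")
})

test_that("BF98 seeds land one per mass on separated point clouds", {
  set.seed(24)
  mass1 <- matrix(rnorm(60 * 3, mean = 0, sd = 0.2), 60)
  mass2 <- matrix(rnorm(60 * 3, mean = 5, sd = 0.2), 60)
  x <- rbind(mass1, mass2)
  seeds <- bf98_seed(x, K = 2, S = 20, seed = 25)
  d_to_1 <- sqrt(rowSums((seeds - matrix(0, 2, 3))^2))
  d_to_2 <- sqrt(rowSums((seeds - matrix(5, 2, 3))^2))
  # one seed within each mass (closer than the between-mass distance)
  expect_equal(sort(unname(c(which.min(d_to_1), which.min(d_to_2)))), c(1, 2))
  expect_lt(min(d_to_1), 1); expect_lt(min(d_to_2), 1)
  # K = 1: the single seed approximates the data mean
  s1 <- bf98_seed(x, K = 1, S = 10, seed = 26)
  expect_lt(sqrt(sum((s1 - colMeans(x))^2)), 1)
  expect_error(bf98_seed(x[1:3, ], K = 5, S = 2), "smaller than K")
})

test_that("planted clusters are recovered and duplicated runs agree", {
  px <- planted_adjusted(n_clusters = 6, per_cluster = 30, n_tissues = 12,
                         reps = 4, seed = 27)
  fit <- kmeans_bf98(px$adj, K = 6, S = 60, seed = 28, n_final_runs = 2)
  expect_gte(adjusted_rand_index(fit$assignment, px$truth[names(fit$assignment)]),
             0.9)
  expect_gte(min(fit$run_ari), 0.99)
  expect_equal(sort(unique(fit$assignment)), 1:6)   # labels contiguous
  expect_gte(fit$within_ss, 0)
})

test_that("BF98 seeding beats the median random-init distortion", {
  px <- planted_adjusted(n_clusters = 5, per_cluster = 20, n_tissues = 10,
                         reps = 3, seed = 29)
  x <- px$adj
  fit <- kmeans_bf98(x, K = 5, S = 40, seed = 30, n_final_runs = 1)
  set.seed(31)
  random_ss <- replicate(10, {
    init <- x[sample(nrow(x), 5), ]
    sagescape:::lloyd_kmeans(x, init)$within_ss
  })
  expect_lte(fit$within_ss, stats::median(random_ss) + 1e-12)
})

test_that("within-cluster dendrograms use average linkage on 1 - correlation", {
  set.seed(32)
  base <- rnorm(10)
  x <- rbind(r1 = base, r2 = base, r3 = -base,
             r4 = rnorm(10), r5 = rnorm(10))
  res <- structure(list(assignment = setNames(rep(1L, 5), rownames(x)),
                        K = 1L, dendrograms = NULL),
                   class = "ClusterResult")
  res <- hclust_within(res, x)
  h <- res$dendrograms$cluster1
  # identical rows merge at height 0; anti-correlated pairs sit at distance 2
  expect_equal(min(h$height), 0, tolerance = 1e-12)
  d <- 1 - cor(t(x))
  expect_equal(d["r1", "r3"], 2, tolerance = 1e-12)
  # oracle: brute-force average-linkage merge heights
  naive_average_linkage <- function(dm) {
    groups <- as.list(seq_len(nrow(dm)))
    heights <- numeric(0)
    while (length(groups) > 1) {
      best <- c(NA, NA); bestd <- Inf
      for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
        dd <- mean(dm[groups[[i]], groups[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(j, i) }
      }
      heights <- c(heights, bestd)
      groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
      groups[[best[2]]] <- NULL
    }
    heights
  }
  expect_equal(sort(h$height), sort(naive_average_linkage(d)),
               tolerance = 1e-10)
  # singleton clusters yield NULL trees
  res2 <- structure(list(assignment = setNames(c(1L, 2L, 2L), c("a", "b", "c")),
                         K = 2L, dendrograms = NULL),
                    class = "ClusterResult")
  x2 <- matrix(rnorm(30), 3, dimnames = list(c("a", "b", "c"), NULL))
  res2 <- hclust_within(res2, x2)
  expect_null(res2$dendrograms$cluster1)
  expect_s3_class(res2$dendrograms$cluster2, "hclust")
})

test_that("dendrograms export as Newick", {
  set.seed(33)
  x <- matrix(rnorm(40), 4, dimnames = list(paste0("t", 1:4), NULL))
  res <- structure(list(assignment = setNames(rep(1L, 4), rownames(x)),
                        K = 1L, dendrograms = NULL), class = "ClusterResult")
  res <- hclust_within(res, x)
  dir <- withr::local_tempdir()
  paths <- write_dendrograms(res, dir)
  expect_true(file.exists(paths[1]))
  tree <- ape::read.tree(paths[1])
  expect_setequal(tree$tip.label, paste0("t", 1:4))
})

test_that("PCA separates structure and supports sample exclusion", {
  # data on a line: first component explains ~all variance
  set.seed(34)
  t_line <- seq(-1, 1, length.out = 12)
  line <- outer(rnorm(30), t_line) + matrix(rnorm(360, sd = 1e-4), 30)
  colnames(line) <- paste0("s", 1:12)
  p <- pca_samples(line)
  expect_gte(p$explained[1], 0.999)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-9)
  # two distant tissue groups: silhouette on PC1 > 0.8
  g <- cbind(matrix(rnorm(50 * 6, 0, 0.3), 50), matrix(rnorm(50 * 6, 8, 0.3), 50))
  colnames(g) <- paste0("s", 1:12)
  pg <- pca_samples(g, n_components = 2)
  pc1 <- pg$scores[, 1]
  lab <- rep(1:2, each = 6)
  sil <- vapply(seq_along(pc1), function(i) {
    a <- mean(abs(pc1[i] - pc1[lab == lab[i]][-match(i, which(lab == lab[i]))]))
    b <- mean(abs(pc1[i] - pc1[lab != lab[i]]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
  # exclusion refits on the remaining samples
  pe <- pca_excluding(g, paste0("s", 1:6))
  expect_equal(rownames(pe$scores), paste0("s", 7:12))
  expect_error(pca_excluding(g, paste0("s", 1:11)), "fewer than 2")
})
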