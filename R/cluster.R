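#' Median-center and unit-normalize rows
#'
#' The standard heatmap adjustment before clustering: each row has its
#' median subtracted and is then scaled to unit Euclidean norm. Rows that
#' are constant (zero norm after centering) are dropped with a warning. The
#' operation is idempotent.
#'
#' @param m numeric matrix (transcripts x samples).
#' @return adjusted matrix, possibly with fewer rows; dropped row names in
#'   attribute `dropped`.
#' @export
adjust_rows <- function(m) {
  med <- apply(m, 1, stats::median)
  centered <- m - med
  norms <- sqrt(rowSums(centered^2))
  drop <- norms == 0
  if (any(drop))
    warning("dropping ", sum(drop), " constant row(s): ",
            paste(utils::head(rownames(m)[drop], 5), collapse = ", "))
  out <- centered[!drop, , drop = FALSE] / norms[!drop]
  attr(out, "dropped") <- rownames(m)[drop]
  out
}

# Squared Euclidean distances between rows of x and rows of centers.
dist2_mat <- function(x, centers) {
  d <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  d[d < 0] <- 0
  d
}

# Lloyd's algorithm with empty-cluster repair (farthest point re-seeded)
# and a per-iteration assertion that the objective never increases.
lloyd_kmeans <- function(x, centers, max_iter = 300L, tol = 1e-6) {
  K <- nrow(centers)
  n <- nrow(x)
  if (K > n) stop("more clusters than data points")
  obj_prev <- Inf
  trace <- numeric(0)
  assign <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    d <- dist2_mat(x, centers)
    assign <- max.col(-d, ties.method = "first")
    mind <- d[cbind(seq_len(n), assign)]
    repeat {                            # farthest point re-seeds empty clusters
      empty <- which(tabulate(assign, K) == 0L)
      if (!length(empty)) break
      far <- which.max(mind)
      assign[far] <- empty[1]
      centers[empty[1], ] <- x[far, ]
      mind[far] <- 0
    }
    obj <- sum(mind)
    if (obj > obj_prev + 1e-8 * (1 + abs(obj_prev)))
      stop("internal error: K-means objective increased (", obj_prev,
           " -> ", obj, ")")
    trace <- c(trace, obj)
    sizes <- tabulate(assign, K)
    new_centers <- rowsum(x, assign, reorder = TRUE) / sizes
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    obj_prev <- obj
    if (shift < tol) break
  }
  d <- dist2_mat(x, centers)
  within <- sum(d[cbind(seq_len(n), assign)])
  list(assignment = assign, centers = centers, within_ss = within,
       iterations = it, objective_trace = trace)
}

#' Bootstrap-refined initial centroids (BF98 seeding)
#'
#' Each of `S` small random subsamples is clustered with K-means, giving
#' `S * K` candidate centroids. K-means is then run over this candidate set,
#' initialized in turn from each subsample's solution, and the centroid set
#' with the smallest distortion over the candidate set is returned as the
#' refined initial seeds.
#'
#' @param x data matrix (rows = observations).
#' @param K number of clusters.
#' @param S number of subsamples (>= 1).
#' @param subsample_fraction fraction of rows per subsample (default 0.1,
#'   floored at `K`).
#' @param seed integer seed.
#' @return K x ncol(x) matrix of initial centroids.
#' @export
bf98_seed <- function(x, K, S = 400L, subsample_fraction = 0.1, seed = NULL) {
  n <- nrow(x)
  m <- max(K, ceiling(subsample_fraction * n))
  if (m > n) m <- n
  if (m < K) stop("subsample size ", m, " smaller than K = ", K)
  if (!is.null(seed)) set.seed(seed)
  solutions <- vector("list", S)
  for (i in seq_len(S)) {
    sub <- x[sample.int(n, m), , drop = FALSE]
    init <- sub[sample.int(m, K), , drop = FALSE]
    solutions[[i]] <- lloyd_kmeans(sub, init)$centers
  }
  cand <- do.call(rbind, solutions)
  best <- NULL
  best_obj <- Inf
  for (i in seq_len(S)) {
    fit <- lloyd_kmeans(cand, solutions[[i]])
    if (fit$within_ss < best_obj) {
      best_obj <- fit$within_ss
      best <- fit$centers
    }
  }
  best
}

#' BF98-seeded K-means clustering
#'
#' Runs Lloyd's K-means from [bf98_seed()] initial centroids to convergence
#' (centroid shift < `tol` or `max_iter` iterations), with empty clusters
#' re-seeded from the farthest point. `n_final_runs` independent seeded runs
#' are executed and their pairwise agreement (adjusted Rand index) reported;
#' the run with the smallest within-cluster sum of squares is returned.
#'
#' @param x adjusted matrix (rows = transcripts), e.g. from [adjust_rows()].
#' @param K number of clusters (default 10).
#' @param S subsample count for seeding (default 400).
#' @param seed integer seed.
#' @param n_final_runs number of duplicated runs (default 2).
#' @param subsample_fraction see [bf98_seed()].
#' @param max_iter,tol Lloyd convergence controls.
#' @return object of class `ClusterResult`: list with `assignment` (named
#'   integer vector), `centroids`, `within_ss`, `K`, `S`, `run_ari`
#'   (pairwise ARI between duplicated runs), `objective_trace`,
#'   `dendrograms` (`NULL` until [hclust_within()] is called).
#' @export
kmeans_bf98 <- function(x, K = 10L, S = 400L, seed = NULL,
                        n_final_runs = 2L, subsample_fraction = 0.1,
                        max_iter = 300L, tol = 1e-6) {
  if (K > nrow(x)) stop("K = ", K, " exceeds the number of rows")
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_final_runs)
  runs <- lapply(run_seeds, function(s) {
    seeds <- bf98_seed(x, K, S, subsample_fraction, seed = s)
    lloyd_kmeans(x, seeds, max_iter = max_iter, tol = tol)
  })
  ari <- if (n_final_runs >= 2) {
    pairs <- utils::combn(n_final_runs, 2)
    apply(pairs, 2, function(ij)
      adjusted_rand_index(runs[[ij[1]]]$assignment, runs[[ij[2]]]$assignment))
  } else numeric(0)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "within_ss"))]]
  assignment <- best$assignment
  names(assignment) <- rownames(x)
  structure(list(assignment = assignment, centroids = best$centers,
                 within_ss = best$within_ss, K = K, S = S,
                 run_ari = ari, objective_trace = best$objective_trace,
                 dendrograms = NULL),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("BF98-seeded K-means: K = %d, S = %d, within-SS = %.4f\n",
              x$K, x$S, x$within_ss))
  cat("cluster sizes:", paste(tabulate(x$assignment, x$K), collapse = " "),
      "\n")
  if (length(x$run_ari))
    cat("duplicated-run ARI:",
        paste(formatC(x$run_ari, digits = 4, format = "f"), collapse = " "),
        "\n")
  invisible(x)
}

#' Hierarchical substructure within each cluster
#'
#' Agglomerative clustering (average linkage, distance = 1 - Pearson
#' correlation across samples) of the members of each K-means cluster,
#' providing the within-cluster ordering used in heatmaps. Singleton
#' clusters get `NULL` trees.
#'
#' @param result a [kmeans_bf98()] `ClusterResult`.
#' @param x the adjusted matrix the clustering was run on.
#' @return the `ClusterResult` with `dendrograms` filled: a list of `hclust`
#'   objects (or `NULL`) indexed by cluster.
#' @export
hclust_within <- function(result, x) {
  stopifnot(inherits(result, "ClusterResult"))
  trees <- lapply(seq_len(result$K), function(k) {
    members <- names(result$assignment)[result$assignment == k]
    if (length(members) < 2) return(NULL)
    d <- stats::as.dist(1 - stats::cor(t(x[members, , drop = FALSE])))
    stats::hclust(d, method = "average")
  })
  names(trees) <- paste0("cluster", seq_len(result$K))
  result$dendrograms <- trees
  result
}

#' Export per-cluster dendrograms as Newick
#'
#' @param result a `ClusterResult` after [hclust_within()].
#' @param dir output directory (created if needed); one
#'   `clusterK.nwk` file per non-trivial cluster.
#' @return invisible character vector of written paths.
#' @export
write_dendrograms <- function(result, dir) {
  stopifnot(inherits(result, "ClusterResult"))
  if (is.null(result$dendrograms)) stop("run hclust_within() first")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(result$dendrograms)) {
    h <- result$dendrograms[[nm]]
    if (is.null(h)) next
    p <- file.path(dir, paste0(nm, ".nwk"))
    ape::write.tree(ape::as.phylo(h), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' PCA of samples with iterative exclusion
#'
#' Column-mean-centered SVD of the sample profiles (samples are the
#' observations). `pca_excluding()` drops named samples and refits, the
#' usual way of "peeling" dominant tissue groups to reveal structure among
#' the remaining samples.
#'
#' @param m log2 expression matrix (transcripts x samples).
#' @param n_components number of components to return scores for (default:
#'   all).
#' @return object of class `PCAResult`: list with `scores` (samples x
#'   components), `explained` (variance fractions, non-increasing),
#'   `loadings`.
#' @export
pca_samples <- function(m, n_components = NULL) {
  if (ncol(m) < 2) stop("PCA needs at least 2 samples")
  p <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components %||% ncol(p$x), ncol(p$x))
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 explained = expl,
                 loadings = p$rotation[, seq_len(k), drop = FALSE]),
            class = "PCAResult")
}

#' @rdname pca_samples
#' @param exclude sample ids to drop before refitting.
#' @export
pca_excluding <- function(m, exclude, n_components = NULL) {
  keep <- setdiff(colnames(m), exclude)
  if (length(keep) < 2)
    stop("excluding these samples leaves fewer than 2")
  pca_samples(m[, keep, drop = FALSE], n_components)
}

#' Sweep K and S for the clustering model-selection grid
#'
#' Runs [kmeans_bf98()] over a grid of (K, S) and reports within-cluster SS
#' and duplicated-run stability for each, supporting the by-eye selection of
#' a clear, reproducible clustering; no automatic chooser is applied.
#'
#' @param x adjusted matrix.
#' @param K_grid,S_grid parameter grids.
#' @param seed integer seed.
#' @param ... passed to [kmeans_bf98()].
#' @return data.frame with `K`, `S`, `within_ss`, `min_run_ari`.
#' @export
cluster_sweep <- function(x, K_grid = c(5L, 10L, 15L), S_grid = c(10L, 100L),
                          seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(K = K_grid, S = S_grid)
  grid$within_ss <- NA_real_
  grid$min_run_ari <- NA_real_
  for (i in seq_len(nrow(grid))) {
    fit <- kmeans_bf98(x, K = grid$K[i], S = grid$S[i],
                       seed = sample.int(.Machine$integer.max, 1), ...)
    grid$within_ss[i] <- fit$within_ss
    grid$min_run_ari[i] <- if (length(fit$run_ari)) min(fit$run_ari) else NA
  }
  grid
}
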