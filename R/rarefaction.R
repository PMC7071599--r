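#' Rarefaction curve for one sample
#'
#' Classical rarefaction: subsample reads without replacement at each depth,
#' map drawn tags to transcripts, and count distinct transcripts discovered;
#' the curve reports the mean (and sd) over `n_reps` independent draws per
#' depth.
#'
#' @param counts named non-negative integer vector: per-tag (or directly
#'   per-transcript) read counts for one sample, e.g. one column of
#'   [count_tags()].
#' @param depth_grid depths to evaluate; defaults to 20 log-spaced points up
#'   to the column total. Values must not exceed the total.
#' @param n_reps subsampling replicates per depth (default 10).
#' @param tag_map optional named list mapping each tag to its transcript
#'   id(s) (e.g. `ref$tag_index`); when `NULL`, names of `counts` are taken
#'   as the discovered entities themselves.
#' @param seed integer seed.
#' @return object of class `RarefactionCurve`: data.frame with `depth`,
#'   `discovered` (mean over reps), `sd`, plus attributes `n_reps` and
#'   `total_distinct`.
#' @export
rarefy <- function(counts, depth_grid = NULL, n_reps = 10L,
                   tag_map = NULL, seed = NULL) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total < 1) stop("sample has no reads")
  if (is.null(depth_grid)) {
    depth_grid <- unique(round(exp(seq(log(1), log(total), length.out = 20))))
  }
  if (any(depth_grid > total))
    stop("depth_grid exceeds the sample total of ", total, " reads")
  if (!is.null(seed)) set.seed(seed)

  species_of <- function(tag_ids) {
    if (is.null(tag_map)) return(tag_ids)
    unique(unlist(tag_map[tag_ids], use.names = FALSE))
  }
  stream <- rep(seq_along(counts), counts)  # read-level multiset
  tag_names <- names(counts)
  draw_one <- function(d) {
    if (d == 0) return(0L)
    drawn <- unique(stream[sample.int(total, d)])
    length(species_of(tag_names[drawn]))
  }
  disc <- vapply(depth_grid, function(d) {
    reps <- vapply(seq_len(n_reps), function(r) draw_one(d), integer(1))
    c(mean(reps), stats::sd(reps))
  }, numeric(2))

  structure(data.frame(depth = depth_grid, discovered = disc[1, ],
                       sd = disc[2, ]),
            class = c("RarefactionCurve", "data.frame"),
            n_reps = n_reps,
            total_distinct = length(species_of(tag_names)))
}

#' Closed-form expected rarefaction curve
#'
#' Expected number of distinct entities discovered when drawing `d` reads
#' without replacement from a library with per-entity counts `n_t`:
#' `sum_t [1 - C(N - n_t, d) / C(N, d)]` (hypergeometric). Used as the
#' analytical reference the Monte-Carlo curve must agree with.
#'
#' @param counts named non-negative integer vector of per-entity counts.
#' @param depths depths at which to evaluate.
#' @return numeric vector of expected discovered counts.
#' @export
expected_discovered <- function(counts, depths) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  vapply(depths, function(d) {
    if (d == 0) return(0)
    sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
  }, numeric(1))
}

#' Saturation index of a rarefaction curve
#'
#' Discovered transcripts at half the maximum depth divided by discovered at
#' full depth (linearly interpolated when the half depth is not on the
#' grid). Values near 1 indicate the library was sequenced to saturation.
#'
#' @param curve a [rarefy()] result with at least 2 depths.
#' @return fraction in (0, 1].
#' @export
saturation_index <- function(curve) {
  stopifnot(inherits(curve, "RarefactionCurve"))
  if (nrow(curve) < 2) stop("curve needs at least 2 depths")
  full <- curve$discovered[which.max(curve$depth)]
  if (full <= 0) stop("degenerate curve: nothing discovered at full depth")
  half <- stats::approx(curve$depth, curve$discovered,
                        xout = max(curve$depth) / 2, rule = 2)$y
  half / full
}
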