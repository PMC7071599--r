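#' Count tags per sample
#'
#' Exact multiset counting of extracted tags into a tags x samples integer
#' matrix; tags absent from a sample get 0. Column order follows the input
#' list.
#'
#' @param tag_lists named list: sample id -> character vector of tags (e.g.
#'   `extract_tags()$tags`).
#' @return integer matrix (tags x samples) with tag rownames.
#' @export
count_tags <- function(tag_lists) {
  stopifnot(is.list(tag_lists), !is.null(names(tag_lists)))
  empty <- names(tag_lists)[lengths(tag_lists) == 0]
  if (length(empty))
    warning("samples with zero tags: ", paste(empty, collapse = ", "))
  all_tags <- sort(unique(unlist(tag_lists, use.names = FALSE)))
  m <- vapply(tag_lists, function(v) {
    tabulate(factor(v, levels = all_tags), nbins = length(all_tags))
  }, integer(length(all_tags)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(all_tags))
  dimnames(m) <- list(all_tags, names(tag_lists))
  m
}

#' Assign tag counts to transcripts
#'
#' A tag mapping to k transcripts contributes `count / k` to each of them
#' (the even-split reading of multi-mapping averaging), so total assigned
#' mass plus unmatched mass equals total tag mass exactly. Tags absent from
#' the reference are tallied as unmatched, never assigned.
#'
#' @param counts tag x sample matrix from [count_tags()].
#' @param ref a [build_tag_reference()] result with matching `tag_len`.
#' @return list with `expression` (transcripts x samples raw matrix over all
#'   reference transcripts, untaggable rows zero; carries
#'   `em_scale = "raw"`) and `unmatched` (named numeric: per-sample
#'   unmatched tag mass).
#' @export
assign_to_transcripts <- function(counts, ref) {
  stopifnot(inherits(ref, "TagReference"))
  if (nrow(counts) > 0 && any(nchar(rownames(counts)) != ref$tag_len))
    stop("counted tag length does not match reference tag_len ", ref$tag_len)
  transcripts <- c(unlist(ref$tag_index, use.names = FALSE), ref$untaggable)
  expr <- matrix(0, nrow = length(transcripts), ncol = ncol(counts),
                 dimnames = list(transcripts, colnames(counts)))
  matched <- rownames(counts) %in% names(ref$tag_index)
  for (tg in rownames(counts)[matched]) {
    ids <- ref$tag_index[[tg]]
    share <- counts[tg, ] / length(ids)
    expr[ids, ] <- expr[ids, , drop = FALSE] +
      matrix(share, nrow = length(ids), ncol = ncol(counts), byrow = TRUE)
  }
  unmatched <- if (any(!matched)) {
    colSums(counts[!matched, , drop = FALSE])
  } else {
    setNames(numeric(ncol(counts)), colnames(counts))
  }
  list(expression = expression_matrix(expr, "raw"), unmatched = unmatched)
}

#' Expression-matrix scale bookkeeping
#'
#' A plain numeric matrix tagged with its scale (`"raw"`,
#' `"quantile_normalized"`, or `"log2"`) via the `em_scale` attribute.
#'
#' @param m numeric matrix with no negative entries.
#' @param scale one of `"raw"`, `"quantile_normalized"`, `"log2"`.
#' @return the matrix with its `em_scale` attribute set.
#' @export
expression_matrix <- function(m, scale = c("raw", "quantile_normalized",
                                           "log2")) {
  scale <- match.arg(scale)
  if (scale != "log2" && any(m < 0)) stop("negative entries not allowed")
  attr(m, "em_scale") <- scale
  m
}

#' @rdname expression_matrix
#' @export
em_scale <- function(m) attr(m, "em_scale") %||% "raw"

#' Quantile normalization
#'
#' Forces every column's empirical distribution onto the across-column mean
#' of sorted values. Ties within a column receive the mean of the reference
#' values their ranks span (fractional average ranks interpolate between the
#' two adjacent reference values). Idempotent, and row/column counts are
#' preserved.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return matrix of the same shape with `em_scale = "quantile_normalized"`.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(m) {
  if (is.null(dim(m)) || ncol(m) < 2)
    stop("quantile normalization needs at least 2 samples")
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(m, 2, function(x) {
    v <- numeric(length(x))
    v[order(x)] <- ref
    # tied input values share the mean of the reference values they span
    stats::ave(v, x, FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  expression_matrix(out, "quantile_normalized")
}

#' Log2 transform with pseudocount
#'
#' @param m raw or quantile-normalized matrix (non-negative).
#' @param pseudocount added before taking log2 (default 1).
#' @return matrix of `log2(x + pseudocount)` with `em_scale = "log2"`.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  if (em_scale(m) == "log2") stop("matrix is already on the log2 scale")
  if (any(m < 0)) stop("negative entries not allowed")
  out <- log2(m + pseudocount)
  attr(out, "em_scale") <- NULL
  expression_matrix(out, "log2")
}
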