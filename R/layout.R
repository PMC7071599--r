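#' Library layout of a multiplexed deepSAGE read
#'
#' Describes the sequence geometry of one library construct and of the
#' single-end read derived from it. The insert is anchored at the 3'-most
#' NlaIII site (`CATG`) of a transcript; the type III enzyme EcoP15I cuts 25
#' nt downstream on one strand and 27 nt on the other, leaving a two-base 5'
#' overhang that is ligated to the barcoded 3' linker and later removed
#' computationally ("digital removal"). Under the defaults the full construct
#' is 47 + 25 + 47 = 119 bp and a 50 bp read covers
#' barcode + 2 degenerate bases + `CATG` + the 19 bp tag.
#'
#' @param barcode_len sample barcode length in nt (default 6).
#' @param degenerate_len number of degenerate overhang bases removed before
#'   the anchor (default 2).
#' @param anchor anchor site sequence, the NlaIII recognition site (default
#'   `"CATG"`).
#' @param tag_len tag length in nt (default 19).
#' @param linker5_len length of the 5' linker carrying the EcoP15I site
#'   (default 47).
#' @param linker3_len length of the barcoded 3' linker, barcode included
#'   (default 47).
#' @param read_len sequencing read length (default 50).
#' @param ecop15i_cut_short,ecop15i_cut_long distance from the EcoP15I
#'   recognition site to the cut on each strand (defaults 25 and 27).
#' @return an object of class `LibraryLayout`.
#' @examples
#' lay <- library_layout()
#' construct_len(lay)  # 119
#' @export
library_layout <- function(barcode_len = 6L,
                           degenerate_len = 2L,
                           anchor = "CATG",
                           tag_len = 19L,
                           linker5_len = 47L,
                           linker3_len = 47L,
                           read_len = 50L,
                           ecop15i_cut_short = 25L,
                           ecop15i_cut_long = 27L) {
  layout <- structure(
    list(barcode_len = as.integer(barcode_len),
         degenerate_len = as.integer(degenerate_len),
         anchor = toupper(anchor),
         tag_len = as.integer(tag_len),
         linker5_len = as.integer(linker5_len),
         linker3_len = as.integer(linker3_len),
         read_len = as.integer(read_len),
         ecop15i_cut_short = as.integer(ecop15i_cut_short),
         ecop15i_cut_long = as.integer(ecop15i_cut_long)),
    class = "LibraryLayout")
  validate_layout(layout)
  layout
}

validate_layout <- function(layout) {
  stopifnot(inherits(layout, "LibraryLayout"))
  with(layout, {
    if (nchar(anchor) + tag_len + degenerate_len != ecop15i_cut_short)
      stop("anchor + tag + degenerate bases must span the short EcoP15I cut (",
           nchar(anchor), "+", tag_len, "+", degenerate_len, " != ",
           ecop15i_cut_short, ")")
    if (ecop15i_cut_long != ecop15i_cut_short + 2L)
      stop("EcoP15I cut distances must differ by the 2 nt overhang")
    if (read_len < barcode_len + degenerate_len + nchar(anchor) + tag_len)
      stop("read too short to cover barcode, degenerate bases, anchor and tag")
    if (!grepl("^[ACGT]+$", anchor))
      stop("anchor must be an A/C/G/T string")
  })
  invisible(layout)
}

#' @rdname library_layout
#' @param layout a `LibraryLayout`.
#' @export
construct_len <- function(layout) {
  validate_layout(layout)
  layout$linker5_len + layout$ecop15i_cut_short + layout$linker3_len
}

# Minimal read length needed to recover a tag.
layout_min_read <- function(layout) {
  layout$barcode_len + layout$degenerate_len + nchar(layout$anchor) +
    layout$tag_len
}

# Fixed arbitrary linker fill (not the real linker oligos); cycled to the
# length needed.
linker_fill <- function(n) {
  base <- "GATCGGAAGAGCACACGTCTGAACTCCAGTCACGATCGGAAGAGCGT"
  paste(rep(substring(base, 1:47, 1:47), length.out = max(n, 0)), collapse = "")
}

#' Assemble the full library construct for one tag
#'
#' Returns the `construct_len(layout)` bp product whose gel band defines the
#' library: 5' linker, then anchor + tag + degenerate overhang (the EcoP15I
#' short-cut span), then the barcoded 3' linker.
#'
#' @param layout a [library_layout()].
#' @param tag tag sequence of length `tag_len`.
#' @param barcode sample barcode of length `barcode_len`.
#' @return single character string of length `construct_len(layout)`.
#' @export
build_construct <- function(layout, tag, barcode) {
  validate_layout(layout)
  if (nchar(tag) != layout$tag_len) stop("tag has wrong length")
  if (nchar(barcode) != layout$barcode_len) stop("barcode has wrong length")
  degen <- paste(rep("N", layout$degenerate_len), collapse = "")
  linker3_rest <- layout$linker3_len - layout$barcode_len
  paste0(linker_fill(layout$linker5_len),
         layout$anchor, toupper(tag), degen,
         toupper(barcode), linker_fill(linker3_rest))
}

#' @export
print.LibraryLayout <- function(x, ...) {
  cat("deepSAGE library layout\n")
  cat(sprintf("  read: barcode(%d) + degenerate(%d) + %s + tag(%d), read_len %d\n",
              x$barcode_len, x$degenerate_len, x$anchor, x$tag_len, x$read_len))
  cat(sprintf("  EcoP15I cut %d/%d nt; construct %d bp\n",
              x$ecop15i_cut_short, x$ecop15i_cut_long, construct_len(x)))
  invisible(x)
}
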