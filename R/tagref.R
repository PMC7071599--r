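#' Virtual tag reference
#'
#' Maps every transcript to the tag its 3'-terminal anchor fragment would
#' produce, and indexes tags back to the transcript set sharing them. The tag
#' is the `tag_len` bases immediately 3' of the 3'-most anchor occurrence;
#' transcripts without an anchor, with fewer than `tag_len` bases downstream
#' of the 3'-most anchor, or with ambiguous bases (N) in the tag region are
#' recorded as untaggable.
#'
#' @param transcripts transcript sequences: a named character vector, a
#'   `DNAStringSet`, or a path to a FASTA file. Sequences are sense-strand
#'   mRNA (5' to 3').
#' @param layout a [library_layout()]; supplies `anchor` and `tag_len`.
#' @return an object of class `TagReference` with fields `tag_index` (named
#'   list: tag -> character vector of transcript ids, in input order),
#'   `untaggable` (character vector of transcript ids), `tag_len`, `anchor`.
#' @examples
#' ref <- build_tag_reference(
#'   c(tx1 = "TTTTCATGAAAAAAAAAAAAAAAAAAACC", tx2 = "CATGAA"),
#'   library_layout())
#' ref$untaggable  # "tx2"
#' @export
build_tag_reference <- function(transcripts, layout = library_layout()) {
  validate_layout(layout)
  seqs <- read_sequences(transcripts)
  if (length(seqs) == 0) stop("no transcript sequences supplied")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every transcript must have an id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate transcript ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  tags <- vapply(seqs, tag_from_sequence, character(1),
                 anchor = layout$anchor, tag_len = layout$tag_len)
  taggable <- tags != "untaggable"
  tag_index <- split(names(seqs)[taggable], tags[taggable])
  structure(list(tag_index = tag_index,
                 untaggable = names(seqs)[!taggable],
                 tag_len = layout$tag_len,
                 anchor = layout$anchor),
            class = "TagReference")
}

# The single place where "what is a transcript's tag" is defined.
# Returns the tag string or "untaggable".
tag_from_sequence <- function(seq, anchor = "CATG", tag_len = 19L) {
  seq <- toupper(seq)
  hits <- gregexpr(anchor, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return("untaggable")
  last <- hits[length(hits)]
  start <- last + nchar(anchor)
  if (start + tag_len - 1L > nchar(seq)) return("untaggable")
  tag <- substr(seq, start, start + tag_len - 1L)
  if (!grepl("^[ACGT]+$", tag)) return("untaggable")
  tag
}

#' Look up a tag in a tag reference
#'
#' Exact-match lookup (no mismatch tolerance); input is normalized to
#' uppercase first.
#'
#' @param ref a [build_tag_reference()] result.
#' @param tag a single tag string of length `ref$tag_len`.
#' @return character vector of transcript ids, possibly empty.
#' @export
tag_lookup <- function(ref, tag) {
  stopifnot(inherits(ref, "TagReference"))
  tag <- toupper(tag)
  if (nchar(tag) != ref$tag_len)
    stop("query has length ", nchar(tag), ", expected ", ref$tag_len)
  ref$tag_index[[tag]] %||% character(0)
}

#' @export
print.TagReference <- function(x, ...) {
  cat(sprintf("TagReference: %d tags over %d transcripts (%d untaggable), %d bp tags after %s\n",
              length(x$tag_index),
              sum(lengths(x$tag_index)) + length(x$untaggable),
              length(x$untaggable), x$tag_len, x$anchor))
  invisible(x)
}

#' Serialize / load a tag reference as TSV
#'
#' Two-column TSV (`tag`, comma-joined transcript ids); untaggable
#' transcripts are stored with tag `"untaggable"`.
#'
#' @param ref a `TagReference`.
#' @param path output (or input) file path.
#' @param layout layout used when reading back.
#' @return `write_tag_reference` returns `path` invisibly;
#'   `read_tag_reference` returns a `TagReference`.
#' @export
write_tag_reference <- function(ref, path) {
  stopifnot(inherits(ref, "TagReference"))
  df <- data.frame(
    tag = c(names(ref$tag_index),
            if (length(ref$untaggable)) "untaggable"),
    transcripts = c(vapply(ref$tag_index, paste, character(1), collapse = ","),
                    if (length(ref$untaggable))
                      paste(ref$untaggable, collapse = ",")),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_reference
#' @export
read_tag_reference <- function(path, layout = library_layout()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  untag <- df$tag == "untaggable"
  tag_index <- strsplit(df$transcripts[!untag], ",", fixed = TRUE)
  names(tag_index) <- df$tag[!untag]
  structure(list(tag_index = tag_index,
                 untaggable = if (any(untag))
                   strsplit(df$transcripts[untag], ",", fixed = TRUE)[[1]]
                 else character(0),
                 tag_len = layout$tag_len,
                 anchor = layout$anchor),
            class = "TagReference")
}

# Accept DNAStringSet, named character, or FASTA path.
read_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    return(as.character(Biostrings::readDNAStringSet(x)))
  }
  if (is.character(x)) return(toupper(x))
  stop("expected a DNAStringSet, named character vector, or FASTA path")
}
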