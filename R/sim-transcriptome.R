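#' Simulate a transcriptome for tag-based profiling
#'
#' Generates random sense-strand transcript sequences at a target GC content.
#' Every non-control transcript is guaranteed to carry at least one anchor
#' site with at least `tag_len` unambiguous bases downstream, so its 19 bp
#' tag is well defined; a configurable fraction of transcripts are emitted as
#' untaggable controls (all anchor occurrences scrubbed).
#'
#' The recorded truth tag is computed with the same rule the tag reference
#' uses (`tag_len` bases 3' of the 3'-most anchor), so simulator truth and
#' [build_tag_reference()] always agree.
#'
#' @param n_transcripts number of transcripts (>= 1).
#' @param length_range integer interval of transcript lengths, inclusive.
#' @param gc GC fraction in (0, 1).
#' @param untaggable_frac fraction of transcripts generated without any
#'   anchor site (default 0.02).
#' @param layout a [library_layout()].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param fasta optional path; when given, sequences are also written as
#'   FASTA.
#' @return list with `sequences` (named character vector), `tag_of` (named
#'   character vector, `"untaggable"` for controls), and `fasta` (path or
#'   `NULL`).
#' @export
simulate_transcriptome <- function(n_transcripts,
                                   length_range = c(400L, 2000L),
                                   gc = 0.5,
                                   untaggable_frac = 0.02,
                                   layout = library_layout(),
                                   seed = NULL,
                                   fasta = NULL) {
  validate_layout(layout)
  if (n_transcripts < 1) stop("n_transcripts must be >= 1")
  anchor_len <- nchar(layout$anchor)
  min_needed <- anchor_len + layout$tag_len
  if (max(length_range) < min_needed)
    stop("length_range too short: need at least ", min_needed,
         " nt for anchor + tag")
  length_range[1] <- max(length_range[1], min_needed)
  if (!is.null(seed)) set.seed(seed)

  lens <- sample(seq(length_range[1], length_range[2]), n_transcripts,
                 replace = TRUE)
  n_untag <- round(untaggable_frac * n_transcripts)
  is_control <- seq_len(n_transcripts) <= n_untag  # deterministic block
  seqs <- random_dna(n_transcripts, lens, gc)

  for (i in seq_len(n_transcripts)) {
    if (is_control[i]) {
      seqs[i] <- scrub_anchor(seqs[i], layout$anchor)
    } else {
      seqs[i] <- ensure_taggable(seqs[i], layout$anchor, layout$tag_len, gc)
    }
  }
  names(seqs) <- sprintf("TX%05d", seq_len(n_transcripts))
  tag_of <- vapply(seqs, tag_from_sequence, character(1),
                   anchor = layout$anchor, tag_len = layout$tag_len)
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  }
  list(sequences = seqs, tag_of = tag_of, fasta = fasta)
}

# Remove every anchor occurrence by flipping its first base; iterate because
# a substitution can create a new occurrence.
scrub_anchor <- function(seq, anchor) {
  repeat {
    hit <- regexpr(anchor, seq, fixed = TRUE)
    if (hit == -1L) return(seq)
    first <- substr(anchor, 1, 1)
    replacement <- setdiff(DNA_BASES, first)[1]
    substr(seq, hit, hit) <- replacement
  }
}

# Guarantee the 3'-most anchor has >= tag_len bases downstream: scrub anchors
# too close to the 3' end, then plant one if none remains.
ensure_taggable <- function(seq, anchor, tag_len, gc) {
  anchor_len <- nchar(anchor)
  L <- nchar(seq)
  last_ok_start <- L - tag_len - anchor_len + 1L
  repeat {
    hits <- gregexpr(anchor, seq, fixed = TRUE)[[1]]
    bad <- hits[hits != -1L & hits > last_ok_start]
    if (length(bad) == 0) break
    first <- substr(anchor, 1, 1)
    replacement <- setdiff(DNA_BASES, first)[1]
    for (b in bad) substr(seq, b, b) <- replacement
  }
  hits <- gregexpr(anchor, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    pos <- sample.int(last_ok_start, 1)
    substr(seq, pos, pos + anchor_len - 1L) <- anchor
    # planting cannot create an anchor starting further 3' than `pos`
  }
  seq
}
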