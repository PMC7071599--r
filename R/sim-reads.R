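#' Simulate multiplexed deepSAGE reads
#'
#' Emits single-end reads with the library geometry of [library_layout()]:
#' sample barcode, `degenerate_len` random overhang bases, the anchor site,
#' the transcript's tag (optionally mutated at a per-base substitution rate),
#' and fixed linker fill up to `read_len`. Per sample, tags are drawn
#' multinomially in proportion to the expression of taggable transcripts;
#' reads from all samples are interleaved as in one multiplexed run.
#'
#' @param expression transcripts x samples abundance matrix (row/col names
#'   required); columns must match `sample_sheet$sample_id`.
#' @param tag_of named character vector mapping transcript id to tag (or
#'   `"untaggable"`), e.g. from [simulate_transcriptome()].
#' @param sample_sheet data.frame with `sample_id`, `tissue`, `barcode`.
#' @param layout a [library_layout()].
#' @param depth reads per sample (>= 1).
#' @param error_rate per-base substitution probability applied to the tag.
#' @param quality Phred score attached to ordinary reads (default 35).
#' @param low_quality_fraction fraction of reads given uniformly poor
#'   qualities (Phred `low_quality`), for exercising the quality filter.
#' @param low_quality Phred score of poor reads (default 2).
#' @param seed integer seed.
#' @param fastq optional path; when given, reads are also written as
#'   Phred+33 FASTQ.
#' @return list with `reads` (data.frame: `id`, `sequence`, `quality`,
#'   `sample_id` truth), `emitted` (per-sample list of tag count tables, the
#'   emission truth), and `fastq` (path or `NULL`).
#' @export
simulate_reads <- function(expression, tag_of, sample_sheet,
                           layout = library_layout(),
                           depth = 10000L,
                           error_rate = 0,
                           quality = 35L,
                           low_quality_fraction = 0,
                           low_quality = 2L,
                           seed = NULL,
                           fastq = NULL) {
  validate_layout(layout)
  validate_sample_sheet(sample_sheet, layout)
  if (depth < 1) stop("depth must be >= 1")
  stopifnot(!is.null(rownames(expression)), !is.null(colnames(expression)))
  if (!all(sample_sheet$sample_id %in% colnames(expression)))
    stop("sample sheet lists samples absent from the expression matrix")
  tag_of <- tag_of[rownames(expression)]
  taggable <- !is.na(tag_of) & tag_of != "untaggable"
  if (!any(taggable)) {
    warning("no taggable transcripts: zero reads emitted")
    return(list(reads = data.frame(id = character(0), sequence = character(0),
                                   quality = character(0),
                                   sample_id = character(0),
                                   stringsAsFactors = FALSE),
                emitted = setNames(vector("list", nrow(sample_sheet)),
                                   sample_sheet$sample_id),
                fastq = fastq))
  }
  if (!is.null(seed)) set.seed(seed)

  tags_taggable <- tag_of[taggable]
  fill <- linker_fill(layout$read_len)  # trimmed per read below
  prefix_len <- layout$barcode_len + layout$degenerate_len
  core_len <- prefix_len + nchar(layout$anchor) + layout$tag_len
  fill_len <- layout$read_len - core_len

  all_seq <- character(0); all_sample <- character(0)
  emitted <- vector("list", nrow(sample_sheet))
  names(emitted) <- sample_sheet$sample_id
  for (i in seq_len(nrow(sample_sheet))) {
    sid <- sample_sheet$sample_id[i]
    probs <- expression[taggable, sid]
    if (sum(probs) <= 0) stop("sample ", sid, " has no positive abundance")
    counts <- as.vector(stats::rmultinom(1, depth, probs))
    tags <- rep(tags_taggable, counts)
    emitted[[i]] <- table(tags)
    if (error_rate > 0) tags <- mutate_bases(tags, error_rate)
    degen <- random_dna_fast(length(tags), layout$degenerate_len)
    reads <- paste0(sample_sheet$barcode[i], degen, layout$anchor, tags,
                    if (fill_len > 0) substr(fill, 1, fill_len) else "")
    all_seq <- c(all_seq, reads)
    all_sample <- c(all_sample, rep(sid, length(reads)))
  }
  n <- length(all_seq)
  ord <- sample.int(n)  # interleave samples as in a multiplexed run
  all_seq <- all_seq[ord]; all_sample <- all_sample[ord]

  qual_hi <- strrep(intToUtf8(quality + 33L), layout$read_len)
  qual_lo <- strrep(intToUtf8(low_quality + 33L), layout$read_len)
  quals <- rep(qual_hi, n)
  if (low_quality_fraction > 0) {
    n_lo <- round(low_quality_fraction * n)
    if (n_lo > 0) quals[sample.int(n, n_lo)] <- qual_lo
  }
  reads <- data.frame(id = sprintf("read%07d", seq_len(n)),
                      sequence = all_seq, quality = quals,
                      sample_id = all_sample, stringsAsFactors = FALSE)
  if (!is.null(fastq)) write_fastq(reads, fastq)
  list(reads = reads, emitted = emitted, fastq = fastq)
}

# Substitute bases independently at rate `rate` (always to a different base).
mutate_bases <- function(seqs, rate) {
  if (length(seqs) == 0 || rate <= 0) return(seqs)
  w <- nchar(seqs[1])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE)
  hit <- which(matrix(stats::runif(length(chars)) < rate, nrow = nrow(chars)))
  if (length(hit)) {
    old <- chars[hit]
    chars[hit] <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1),
                         character(1))
  }
  apply(chars, 1, paste, collapse = "")
}

# Uniform-composition random DNA, vectorized for many short strings.
random_dna_fast <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
}

#' Read / write FASTQ (Phred+33)
#'
#' Thin wrappers over Biostrings quality-scaled string sets, exchanging the
#' package's read data.frame (`id`, `sequence`, `quality`).
#'
#' @param reads data.frame with `id`, `sequence`, `quality`.
#' @param path FASTQ path.
#' @return `read_fastq` returns the reads data.frame; `write_fastq` returns
#'   `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality))
  names(x) <- reads$id
  # Biostrings warns about dropping (empty) metadata columns; cosmetic
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(id = names(x),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}
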