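#' Read transcript sequences from a FASTA file
#'
#' Loads a FASTA file into a transcript set: a named character vector of
#' uppercase nucleotide sequences. Identifiers are truncated at the first
#' whitespace, sequences are uppercased, and the alphabet is restricted to
#' A/C/G/T/N. All downstream coordinates in the package are 0-based,
#' half-open, on the transcript's 5'->3' strand.
#'
#' @param path Path to a FASTA file. An empty file yields an empty set.
#' @return Named character vector of sequences (class `transcript_set`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) return(transcript_set(character(0)))
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  x <- toupper(as.character(seqs))
  names(x) <- ids
  transcript_set(x)
}

#' Construct and validate a transcript set
#'
#' @param x Named character vector of nucleotide sequences.
#' @return `x`, validated, with class `transcript_set`.
#' @export
transcript_set <- function(x) {
  nm <- names(x)
  x <- toupper(as.character(x))
  names(x) <- nm
  if (length(x) > 0) {
    if (is.null(names(x)) || any(names(x) == "") || anyNA(names(x)))
      stop("transcript_set: all sequences must be named")
    if (anyDuplicated(names(x)))
      stop("transcript_set: duplicate transcript ids: ",
           paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    if (any(nchar(x) == 0))
      stop("transcript_set: empty sequences are not allowed")
    if (any(grepl("[^ACGTN]", x)))
      stop("transcript_set: sequences restricted to A/C/G/T/N")
  }
  class(x) <- c("transcript_set", class(x))
  x
}

#' Write a transcript set to FASTA
#'
#' @param x A `transcript_set` (named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::BStringSet(unclass(x))
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read annotation intervals from a BED file
#'
#' BED is 0-based half-open and that convention is preserved bit-exactly.
#' BED6 strand is kept; BED3 records default to '+' with a warning. Empty
#' (zero-width) intervals are a format error.
#'
#' @param path Path to a BED3/BED6 file.
#' @return A data.frame (class `interval_set`) with columns
#'   `ref`, `start` (0-based), `end` (exclusive), `strand`, `label`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (any(IRanges::width(gr) <= 0))
    stop("read_bed: zero-width interval (end <= start) in ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    warning("read_bed: records without strand default to '+'")
    strand[strand == "*"] <- "+"
  }
  label <- if (!is.null(gr$name)) as.character(gr$name) else rep(".", length(gr))
  label[is.na(label)] <- "."
  interval_set(data.frame(
    ref = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    label = label,
    stringsAsFactors = FALSE
  ))
}

#' Read annotation intervals from a GFF3 file
#'
#' Converts GFF3 features to the package's 0-based half-open interval set,
#' optionally restricted to given feature types (e.g. `"CDS"`).
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Optional character vector of `type` values to keep.
#' @return An `interval_set` data.frame (see [read_bed()]).
#' @export
read_gff <- function(path, feature_types = NULL) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_types))
    gr <- gr[as.character(gr$type) %in% feature_types]
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  label <- as.character(gr$type)
  interval_set(data.frame(
    ref = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    label = label,
    stringsAsFactors = FALSE
  ))
}

#' Construct and validate an interval set
#'
#' @param df data.frame with columns `ref`, `start`, `end`, `strand`, `label`.
#' @return `df` with class `interval_set`.
#' @export
interval_set <- function(df) {
  stopifnot(all(c("ref", "start", "end", "strand", "label") %in% names(df)))
  if (nrow(df) > 0) {
    if (any(df$start < 0) || any(df$end <= df$start))
      stop("interval_set: require 0 <= start < end")
    if (!all(df$strand %in% c("+", "-")))
      stop("interval_set: strand must be '+' or '-'")
  }
  class(df) <- unique(c("interval_set", class(df)))
  df
}

#' Read a transcript-aligned read table
#'
#' The read table is a TSV with mandatory header
#' `transcript  pos5  length  count`: one row per (transcript, 5'-end
#' position, read length) with an aggregated count. `pos5` is the 0-based
#' 5'-end position of the read on the transcript. `library_size` is the
#' total number of mapped reads in the library: it is supplied, not inferred,
#' because the RPKM denominator is the global mapped total, which exceeds
#' the reads on the analysed transcripts.
#'
#' @param path Path to the TSV file.
#' @param library_size Total mapped reads (positive number).
#' @return A list with elements `reads` (data.frame) and `library_size`,
#'   class `read_table`.
#' @export
read_reads <- function(path, library_size) {
  if (!file.exists(path)) stop("read table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript", "pos5", "length", "count")
  if (!all(req %in% names(df)))
    stop("read_reads: header must contain columns: ", paste(req, collapse = ", "))
  read_table(df[req], library_size)
}

#' Construct and validate a read table
#'
#' @param reads data.frame with columns `transcript`, `pos5`, `length`, `count`.
#' @param library_size Total mapped reads in the library.
#' @return List of class `read_table`.
#' @export
read_table <- function(reads, library_size) {
  stopifnot(is.data.frame(reads),
            all(c("transcript", "pos5", "length", "count") %in% names(reads)))
  if (!is.numeric(library_size) || length(library_size) != 1 || library_size <= 0)
    stop("read_table: library_size must be a single positive number")
  if (nrow(reads) > 0) {
    if (any(reads$pos5 < 0)) stop("read_table: pos5 must be >= 0")
    if (any(reads$count < 0)) stop("read_table: counts must be >= 0")
    if (any(reads$length < 1 | reads$length > 200))
      stop("read_table: read lengths must be in [1, 200]")
  }
  structure(list(reads = reads, library_size = library_size),
            class = "read_table")
}

#' Write a read table to TSV
#'
#' @param x A `read_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(x, path) {
  stopifnot(inherits(x, "read_table"))
  utils::write.table(x$reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
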