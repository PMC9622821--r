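#' Discover candidate small ORFs on transcripts
#'
#' Scans every transcript for AUG->STOP open reading frames, reading each AUG
#' through to the first in-frame stop codon. ORFs are retained when the codon
#' count (AUG through the last sense codon, stop excluded) lies within
#' `[min_codons, max_codons]`. Among retained ORFs that share a stop codon in
#' the same frame on the same sequence, only the 5'-most AUG is kept (internal
#' ORFs are removed); duplicate coordinates are collapsed. ORFs containing N
#' are discarded with a message.
#'
#' @param transcripts A [transcript_set()] (named character vector also
#'   accepted).
#' @param min_codons,max_codons Inclusive codon-count bounds (stop excluded).
#' @param both_strands Scan the reverse complement as well (6-frame mode, used
#'   when building peptide databases from EST-style input). Reverse-strand
#'   coordinates refer to the reverse-complemented sequence and carry
#'   `strand = "-"`.
#' @return data.frame with columns `orf_id`, `transcript`, `start` (0-based,
#'   at the A of AUG), `end` (exclusive, past the stop codon), `strand`,
#'   `n_codons`, `nt_seq`, `peptide`.
#' @export
find_orfs <- function(transcripts, min_codons = 10, max_codons = 150,
                      both_strands = FALSE) {
  if (!inherits(transcripts, "transcript_set"))
    transcripts <- transcript_set(transcripts)
  out <- vector("list", length(transcripts) * (1L + both_strands))
  k <- 0L
  n_dropped_n <- 0L
  for (id in names(transcripts)) {
    strands <- if (both_strands) c("+", "-") else "+"
    for (strand in strands) {
      seq <- unclass(transcripts)[[id]]
      if (strand == "-") seq <- revcomp(seq)
      res <- .scan_orfs_one(seq, min_codons, max_codons)
      if (is.null(res)) next
      has_n <- grepl("N", res$nt_seq, fixed = TRUE)
      n_dropped_n <- n_dropped_n + sum(has_n)
      res <- res[!has_n, , drop = FALSE]
      if (nrow(res) == 0) next
      res$transcript <- id
      res$strand <- strand
      k <- k + 1L
      out[[k]] <- res
    }
  }
  if (n_dropped_n > 0)
    message("find_orfs: dropped ", n_dropped_n, " ORF(s) containing N")
  if (k == 0L) return(.empty_orf_df())
  df <- do.call(rbind, out[seq_len(k)])
  df$peptide <- vapply(df$nt_seq, translate_nt, character(1), USE.NAMES = FALSE)
  df$orf_id <- paste(df$transcript,
                     ifelse(df$strand == "+", "", "rc"),
                     df$start, df$end, sep = "_")
  df$orf_id <- sub("__", "_", df$orf_id, fixed = TRUE)
  rownames(df) <- NULL
  df[c("orf_id", "transcript", "start", "end", "strand",
       "n_codons", "nt_seq", "peptide")]
}

.empty_orf_df <- function() {
  data.frame(orf_id = character(0), transcript = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             n_codons = integer(0), nt_seq = character(0),
             peptide = character(0), stringsAsFactors = FALSE)
}

# one sequence, forward strand; returns start/end/n_codons/nt_seq or NULL
.scan_orfs_one <- function(seq, min_codons, max_codons) {
  n <- nchar(seq)
  if (n < (min_codons + 1L) * 3L) return(NULL)
  atg <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (atg[1] == -1L) return(NULL)
  rows <- list()
  for (f in 0:2) {
    starts_f <- atg[(atg - 1L) %% 3L == f]
    if (length(starts_f) == 0) next
    cod_pos <- seq.int(f + 1L, n - 2L, 3L)
    codons <- substring(seq, cod_pos, cod_pos + 2L)
    stops <- cod_pos[codons %in% .STOP_CODONS]
    if (length(stops) == 0) next
    idx <- findInterval(starts_f, stops) + 1L        # first stop after AUG
    ok <- idx <= length(stops)
    starts_f <- starts_f[ok]
    stop_f <- stops[idx[ok]]
    n_codons <- (stop_f - starts_f) %/% 3L
    keep <- n_codons >= min_codons & n_codons <= max_codons
    if (!any(keep)) next
    starts_f <- starts_f[keep]; stop_f <- stop_f[keep]
    # internal-ORF rule: one ORF per shared stop, 5'-most AUG wins
    first <- !duplicated(stop_f)  # starts_f ascending within frame
    rows[[length(rows) + 1L]] <- data.frame(
      start = starts_f[first] - 1L,
      end = stop_f[first] + 2L,
      n_codons = n_codons[keep][first],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[c("start", "end")]), , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  df$nt_seq <- substring(seq, df$start + 1L, df$end)
  df
}

#' Remove ORFs overlapping annotated coding sequences or uORFs
#'
#' Any ORF with at least 1 bp of same-strand overlap with either interval set
#' is removed (the semantics of `bedtools intersect -v -s`). Half-open
#' abutment is not an overlap. Intervals must be on the same (transcript)
#' coordinate system as the ORFs.
#'
#' @param orfs ORF data.frame from [find_orfs()].
#' @param cds,uorfs Optional [interval_set()]s of annotated CDS and uORF
#'   intervals.
#' @return The filtered ORF data.frame.
#' @export
filter_against_annotation <- function(orfs, cds = NULL, uorfs = NULL) {
  ann <- do.call(rbind, Filter(Negate(is.null), list(
    if (!is.null(cds)) as.data.frame(cds)[c("ref", "start", "end", "strand")],
    if (!is.null(uorfs)) as.data.frame(uorfs)[c("ref", "start", "end", "strand")])))
  if (is.null(ann) || nrow(ann) == 0 || nrow(orfs) == 0) return(orfs)
  orf_gr <- GenomicRanges::GRanges(
    seqnames = orfs$transcript,
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = orfs$strand)
  ann_gr <- GenomicRanges::GRanges(
    seqnames = ann$ref,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  hit <- GenomicRanges::countOverlaps(orf_gr, ann_gr, minoverlap = 1L,
                                      ignore.strand = FALSE) > 0
  orfs[!hit, , drop = FALSE]
}
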