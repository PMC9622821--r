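#' Reads per kilobase per million mapped reads
#'
#' `count / (len_nt/1000) / (library_size/1e6)`. The denominator library
#' size is the library's total mapped reads, supplied explicitly.
#'
#' @param count Read count attributed to the feature (vectorised).
#' @param len_nt Feature length in nucleotides (> 0).
#' @param library_size Total mapped reads (> 0).
#' @return RPKM values.
#' @export
rpkm <- function(count, len_nt, library_size) {
  if (any(len_nt <= 0)) stop("rpkm: feature length must be > 0")
  if (any(library_size <= 0)) stop("rpkm: library size must be > 0")
  count / (len_nt / 1000) / (library_size / 1e6)
}

#' Count reads attributed to each ORF
#'
#' A read belongs to an ORF when its 5' end lies in the ORF body
#' `[start, end)`. For footprint libraries restrict `lengths` to the RPF
#' range (26-36 nt); for RNA-seq leave `lengths = NULL`.
#'
#' @param reads A [read_table()].
#' @param orfs ORF data.frame.
#' @param lengths Optional read-length filter.
#' @return Named numeric vector of counts, one per `orf_id` (zeros included).
#' @export
orf_read_counts <- function(reads, orfs, lengths = NULL) {
  stopifnot(inherits(reads, "read_table"))
  rd <- reads$reads
  if (!is.null(lengths)) rd <- rd[rd$length %in% lengths, , drop = FALSE]
  out <- stats::setNames(numeric(nrow(orfs)), orfs$orf_id)
  if (nrow(rd) == 0 || nrow(orfs) == 0) return(out)
  m <- merge(rd, orfs[c("orf_id", "transcript", "start", "end")],
             by = "transcript")
  m <- m[m$pos5 >= m$start & m$pos5 < m$end, , drop = FALSE]
  if (nrow(m) > 0) {
    agg <- tapply(m$count, m$orf_id, sum)
    out[names(agg)] <- agg
  }
  out
}

#' Classify per-stage translation status from two replicas
#'
#' The decision cascade, evaluated per ORF and stage from replicas T and B:
#' *transcribed* when RNA-seq RPKM > 1 in either replica; *ribo-bound* when
#' additionally footprint RPKM > 1 in **both** replicas; framing is only
#' consulted once the ribo-bound condition holds. A bound ORF framed in both
#' replicas is `robust`, framed in exactly one is `limited`, framed in
#' neither is `ribo_bound_only`; a transcribed ORF that is not bound is
#' `transcribed_only`; otherwise `not_expressed`.
#'
#' @param rna_T,rna_B RNA-seq RPKM in replicas T and B (vectorised).
#' @param fp_T,fp_B Footprint RPKM in replicas T and B.
#' @param framed_T,framed_B Logical: framing in at least one RPF length in
#'   that replica.
#' @param rpkm_threshold Expression threshold (default 1).
#' @return Character vector of statuses.
#' @export
classify_status <- function(rna_T, rna_B, fp_T, fp_B, framed_T, framed_B,
                            rpkm_threshold = 1) {
  transcribed <- pmax(rna_T, rna_B) > rpkm_threshold
  bound <- transcribed & fp_T > rpkm_threshold & fp_B > rpkm_threshold
  n_framed <- as.integer(framed_T) + as.integer(framed_B)
  ifelse(!transcribed, "not_expressed",
  ifelse(!bound, "transcribed_only",
  ifelse(n_framed == 2L, "robust",
  ifelse(n_framed == 1L, "limited", "ribo_bound_only"))))
}

#' Summarise stage specificity of transcription and translation
#'
#' Given per-stage status calls for each ORF, reports whether transcription
#' (any status above `not_expressed`) and translation (`limited` or
#' `robust`) are `constitutive` (all stages), `stage_specific` (some but not
#' all), or `never`.
#'
#' @param status_df data.frame with columns `orf_id`, `stage`, `status`.
#' @return data.frame with `orf_id`, `transcription`, `translation`.
#' @export
stage_summary <- function(status_df) {
  summarise_one <- function(flags) {
    if (all(flags)) "constitutive" else if (any(flags)) "stage_specific" else "never"
  }
  ids <- unique(status_df$orf_id)
  res <- lapply(ids, function(id) {
    s <- status_df$status[status_df$orf_id == id]
    data.frame(orf_id = id,
               transcription = summarise_one(s != "not_expressed"),
               translation = summarise_one(s %in% c("limited", "robust")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Translational efficiency
#'
#' TE = footprint RPKM / RNA RPKM, the ratio of translation to transcription,
#' computed from replica-averaged RPKMs per stage.
#'
#' @param rpkm_fp,rpkm_rna Footprint and RNA RPKM (vectorised);
#'   `rpkm_rna` must be > 0.
#' @return TE values.
#' @export
translational_efficiency <- function(rpkm_fp, rpkm_rna) {
  if (any(rpkm_rna <= 0))
    stop("translational_efficiency: rpkm_rna must be > 0")
  rpkm_fp / rpkm_rna
}

#' Z-ratios of translational-efficiency change between two stages
#'
#' For a table of ORFs with TE in a pair of time-contiguous stages (the
#' constitutively transcribed set): `x = log10(TE)` per stage; z-scores are
#' taken within each stage across ORFs; the Z-ratio is the per-ORF z-score
#' difference standardised by the SD of those differences. `|Z-ratio| >= 1.5`
#' (empirical threshold) flags a significant regulatory event.
#'
#' @param te_table data.frame with columns `orf_id`, `te_a`, `te_b`
#'   (TE at the earlier and later stage; both must be > 0).
#' @param threshold Significance threshold on `|z_ratio|`.
#' @param transition Optional label (e.g. `"Early->Mid"`).
#' @return data.frame with `orf_id`, `transition`, `te_a`, `te_b`, `z_a`,
#'   `z_b`, `z_ratio`, `significant`.
#' @export
te_z_ratios <- function(te_table, threshold = 1.5, transition = NA_character_) {
  stopifnot(all(c("orf_id", "te_a", "te_b") %in% names(te_table)))
  if (nrow(te_table) < 3)
    stop("te_z_ratios: need at least 3 ORFs")
  if (any(te_table$te_a <= 0) || any(te_table$te_b <= 0))
    stop("te_z_ratios: TE must be > 0 (zero-FP ORFs are excluded upstream)")
  xa <- log10(te_table$te_a); xb <- log10(te_table$te_b)
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
    stop("te_z_ratios: zero variance of log10(TE) within a stage")
  za <- (xa - mean(xa)) / stats::sd(xa)
  zb <- (xb - mean(xb)) / stats::sd(xb)
  d <- zb - za
  if (stats::sd(d) == 0)
    stop("te_z_ratios: zero variance of z-score differences")
  zr <- d / stats::sd(d)
  data.frame(orf_id = te_table$orf_id, transition = transition,
             te_a = te_table$te_a, te_b = te_table$te_b,
             z_a = za, z_b = zb, z_ratio = zr,
             significant = abs(zr) >= threshold, stringsAsFactors = FALSE)
}
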