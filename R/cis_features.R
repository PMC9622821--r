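# Kozak scored positions relative to the A of AUG (0-based offsets):
# -5..-1 upstream, +4..+6 = the codon right after the start codon.
.KOZAK_OFFSETS <- c(-5L, -4L, -3L, -2L, -1L, 3L, 4L, 5L)
.NUC <- c("A", "C", "G", "T")

#' Extract the 8-nt Kozak context around each ORF start
#'
#' The scored context covers positions -5..-1 and +4..+6 around the start
#' codon (the AUG itself, positions +1..+3, is excluded). ORFs whose context
#' window runs off the transcript, or whose context contains N, yield NA.
#'
#' @param transcripts A [transcript_set()].
#' @param orfs ORF data.frame with `transcript` and `start`.
#' @return Character vector of 8-mers (or NA), named by `orf_id`.
#' @export
extract_kozak_context <- function(transcripts, orfs) {
  seqs <- unclass(transcripts)
  out <- stats::setNames(rep(NA_character_, nrow(orfs)), orfs$orf_id)
  for (i in seq_len(nrow(orfs))) {
    seq <- seqs[[orfs$transcript[i]]]
    pos <- orfs$start[i] + .KOZAK_OFFSETS + 1L   # 1-based
    if (pos[1] < 1L || pos[length(pos)] > nchar(seq)) next
    ctx <- paste(substring(seq, pos, pos), collapse = "")
    if (!grepl("[^ACGT]", ctx)) out[i] <- ctx
  }
  out
}

#' Build a Kozak position-specific log-odds model
#'
#' From a training set of canonical start contexts (8-mers over positions
#' -5..-1, +4..+6), per-position nucleotide frequencies are estimated with a
#' pseudocount of 1 per nucleotide; the background is the position-independent
#' pooled frequency over all positions of the same contexts (same
#' pseudocounts). Weights are natural-log odds `log(f/g)`. The mean raw score
#' of the training contexts is stored so scores can be reported centered
#' (canonical average = 0).
#'
#' @param canonical_contexts Character vector of 8-mers (alphabet ACGT).
#' @param pseudocount Added per nucleotide per position (default 1).
#' @return List of class `kozak_model`: `weights` (4 x 8 matrix, rows ACGT),
#'   `background`, `canonical_mean`, `offsets`.
#' @export
build_kozak_model <- function(canonical_contexts, pseudocount = 1) {
  ctx <- canonical_contexts[!is.na(canonical_contexts)]
  if (length(ctx) < 1) stop("build_kozak_model: need at least one context")
  if (any(nchar(ctx) != 8)) stop("build_kozak_model: contexts must be 8-mers")
  if (any(grepl("[^ACGT]", ctx)))
    stop("build_kozak_model: contexts restricted to A/C/G/T")
  n <- length(ctx)
  counts <- matrix(0, nrow = 4, ncol = 8, dimnames = list(.NUC, NULL))
  chars <- matrix(unlist(strsplit(ctx, NULL)), nrow = n, byrow = TRUE)
  for (j in 1:8) {
    tab <- table(factor(chars[, j], levels = .NUC))
    counts[, j] <- as.numeric(tab)
  }
  f <- (counts + pseudocount) / (n + 4 * pseudocount)
  # pooled background with the same per-position pseudocounts (8 positions),
  # so that a position whose usage equals the pooled usage has weight 0
  g <- (rowSums(counts) + 8 * pseudocount) / (8 * (n + 4 * pseudocount))
  weights <- log(f / g)
  model <- structure(list(weights = weights, background = g,
                          canonical_mean = 0, offsets = .KOZAK_OFFSETS),
                     class = "kozak_model")
  model$canonical_mean <- mean(kozak_score(ctx, model, centered = FALSE))
  model
}

#' Score a start context against a Kozak model
#'
#' Sum of the position-specific log-odds weights of the observed
#' nucleotides; with `centered = TRUE` (the reporting convention) the mean
#' raw score of the model's training contexts is subtracted, so 0 is the
#' canonical average.
#'
#' @param context Character vector of 8-mers (NA passes through as NA).
#' @param model A `kozak_model`.
#' @param centered Subtract the canonical mean (default TRUE).
#' @return Numeric scores.
#' @export
kozak_score <- function(context, model, centered = TRUE) {
  stopifnot(inherits(model, "kozak_model"))
  ok <- !is.na(context)
  if (any(nchar(context[ok]) != 8)) stop("kozak_score: contexts must be 8-mers")
  if (any(grepl("[^ACGT]", context[ok])))
    stop("kozak_score: contexts restricted to A/C/G/T")
  out <- rep(NA_real_, length(context))
  if (any(ok)) {
    chars <- matrix(unlist(strsplit(context[ok], NULL)), ncol = 8, byrow = TRUE)
    sc <- numeric(sum(ok))
    for (j in 1:8) sc <- sc + model$weights[cbind(match(chars[, j], .NUC), j)]
    out[ok] <- sc
  }
  if (centered) out <- out - model$canonical_mean
  out
}

#' Cistronic rank of ORFs within their transcript
#'
#' The 5'->3' position rank of each ORF among **all** predicted ORFs of its
#' transcript, regardless of translation status: 1 + the number of predicted
#' ORFs with strictly smaller start (ties share a rank).
#'
#' @param orfs ORF data.frame with `orf_id`, `transcript`, `start`.
#' @return `orfs` with an added integer column `cistronic_rank`.
#' @export
cistronic_rank <- function(orfs) {
  rk <- integer(nrow(orfs))
  for (tx in unique(orfs$transcript)) {
    i <- which(orfs$transcript == tx)
    s <- orfs$start[i]
    rk[i] <- vapply(s, function(x) 1L + sum(s < x), integer(1))
  }
  orfs$cistronic_rank <- rk
  orfs
}

#' MILC codon-usage bias of an ORF against a reference usage
#'
#' MILC (Measure Independent of Length and Composition) compares the
#' within-family synonymous-codon usage of a sequence with a reference
#' usage: per synonymous family a, `M_a = 2 * sum_c o_c * ln(f_c / g_c)`
#' where `o_c` are observed codon counts, `f_c` the observed within-family
#' frequencies and `g_c` the reference within-family frequencies. MILC is
#' `sum_a M_a / L - C` with `L` the number of (sense) codons used and
#' `C = sum_a (r_a - 1) / L` over the families observed, which removes the
#' expected per-codon contribution under the reference so a sequence drawn
#' from the reference usage scores near 0. Single-codon families (Met, Trp)
#' contribute 0; stop codons are excluded.
#'
#' @param orf_codons Character vector of codons (or one nucleotide string
#'   with length divisible by 3).
#' @param reference_usage Named numeric vector of reference codon counts (or
#'   frequencies) covering the sense codons. Codons observed but absent from
#'   the reference fall back to a 0.5 pseudocount within the family, with a
#'   message.
#' @return List of class `milc_result`: `milc`, `M` (per family), `r`
#'   (family sizes), `L`, `C`, `observed`, `f`, `g`.
#' @export
milc <- function(orf_codons, reference_usage) {
  if (length(orf_codons) == 1 && nchar(orf_codons) > 3) {
    n <- nchar(orf_codons)
    stopifnot(n %% 3 == 0)
    orf_codons <- substring(orf_codons, seq(1, n, 3), seq(3, n, 3))
  }
  orf_codons <- toupper(orf_codons)
  orf_codons <- orf_codons[!(orf_codons %in% .STOP_CODONS)]
  if (length(orf_codons) == 0) stop("milc: need at least one sense codon")
  fams <- .codon_families()
  obs <- table(factor(orf_codons, levels = .sense_codons()))
  obs <- stats::setNames(as.numeric(obs), names(obs))
  L <- sum(obs)
  ref <- stats::setNames(rep(0, length(obs)), names(obs))
  common <- intersect(names(reference_usage), names(ref))
  ref[common] <- reference_usage[common]
  M <- r <- stats::setNames(numeric(length(fams)), names(fams))
  f_all <- g_all <- stats::setNames(rep(NA_real_, length(obs)), names(obs))
  C_sum <- 0
  for (a in names(fams)) {
    cods <- fams[[a]]
    r[a] <- length(cods)
    o <- obs[cods]
    if (sum(o) == 0) next
    C_sum <- C_sum + unname(r[a]) - 1
    if (r[a] == 1) next                      # Met / Trp contribute 0
    g_ref <- ref[cods]
    if (any(o > 0 & g_ref == 0)) {
      message("milc: codon(s) absent from reference in family ", a,
              "; applying 0.5 pseudocount")
      g_ref <- g_ref + 0.5
    }
    g <- g_ref / sum(g_ref)
    f <- o / sum(o)
    g_all[cods] <- g; f_all[cods] <- f
    nz <- o > 0
    M[a] <- 2 * sum(o[nz] * log(f[nz] / g[nz]))
  }
  C <- C_sum / L
  structure(list(milc = unname(sum(M)) / L - C, M = M, r = r, L = L, C = C,
                 observed = obs, f = f_all, g = g_all),
            class = "milc_result")
}

#' Reference codon usage from a set of ORFs
#'
#' Pools sense-codon counts across sequences (typically all annotated
#' canonical ORFs) for use as the MILC control set.
#'
#' @param nt_seqs Character vector of in-frame nucleotide sequences.
#' @return Named numeric vector of codon counts over the 61 sense codons.
#' @export
codon_usage <- function(nt_seqs) {
  all_cod <- unlist(lapply(nt_seqs, function(s) {
    n <- nchar(s)
    substring(s, seq(1, n - 2, 3), seq(3, n, 3))
  }))
  all_cod <- all_cod[!(all_cod %in% .STOP_CODONS)]
  tab <- table(factor(all_cod, levels = .sense_codons()))
  stats::setNames(as.numeric(tab), names(tab))
}

#' Pooled amino-acid usage profile
#'
#' @param peptides Non-empty character vector of peptide sequences
#'   (one-letter code).
#' @return Named numeric 20-vector of amino-acid frequencies (sums to 1).
#' @export
aa_usage_profile <- function(peptides) {
  if (length(peptides) == 0 || all(nchar(peptides) == 0))
    stop("aa_usage_profile: empty input")
  aa20 <- sort(setdiff(unique(unname(.codon_table())), "*"))
  chars <- unlist(strsplit(paste(peptides, collapse = ""), NULL))
  tab <- table(factor(chars, levels = aa20))
  freqs <- as.numeric(tab) / sum(tab)
  stats::setNames(freqs, aa20)
}
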