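# Degeneracy classification cache: 61 sense codons x 3 positions.
.degeneracy_env <- new.env(parent = emptyenv())

.degeneracy_table <- function() {
  if (!is.null(.degeneracy_env$tab)) return(.degeneracy_env$tab)
  gc <- .codon_table()
  sense <- .sense_codons()
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  tab <- matrix(0L, nrow = length(sense), ncol = 3,
                dimnames = list(sense, NULL))
  for (cod in sense) {
    ch <- strsplit(cod, NULL)[[1]]
    for (p in 1:3) {
      syn <- 0L; ts_syn <- FALSE
      for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
        mut <- ch; mut[p] <- b
        mcod <- paste(mut, collapse = "")
        if (gc[mcod] == gc[cod] && gc[mcod] != "*") {
          syn <- syn + 1L
          if (is_transition(ch[p], b)) ts_syn <- TRUE
        }
      }
      # 4-fold: all three substitutions synonymous; 2-fold: the transition
      # is synonymous (three-fold Ile third positions collapse here);
      # otherwise non-degenerate.
      tab[cod, p] <- if (syn == 3L) 4L else if (ts_syn) 2L else 0L
    }
  }
  .degeneracy_env$tab <- tab
  tab
}

#' Degeneracy class of each codon position
#'
#' A codon position is 4-fold degenerate when all three nucleotide
#' substitutions at it are synonymous, 2-fold when exactly the transition is
#' synonymous (three-fold degenerate Ile third positions collapse to 2-fold
#' by convention), and non-degenerate (0-fold) otherwise. Derived by
#' enumeration over the standard genetic code, not a lookup table.
#'
#' @param codon A sense codon (stop codons are an error).
#' @return Integer vector of length 3 with values in `{0, 2, 4}`.
#' @export
classify_degeneracy <- function(codon) {
  codon <- toupper(codon)
  if (codon %in% .STOP_CODONS) stop("classify_degeneracy: stop codon")
  tab <- .degeneracy_table()
  if (!codon %in% rownames(tab)) stop("classify_degeneracy: invalid codon ", codon)
  unname(tab[codon, ])
}

#' Pairwise dN/dS by the Li (1993) counting method
#'
#' Sites of the two aligned coding sequences are classified as
#' non-degenerate (L0), two-fold (L2) or four-fold (L4) degenerate, with
#' counts averaged between the sequences; observed differences are split
#' into transitions and transversions per class (a differing position whose
#' class differs between the two sequences contributes 1/2 to each class).
#' Kimura-type distances per class `i` are
#' `A_i = -1/2 ln(1 - 2P_i - Q_i) + 1/4 ln(1 - 2Q_i)` (transitional) and
#' `B_i = -1/2 ln(1 - 2Q_i)` (transversional), and the Li (1993) /
#' Pamilo-Bianchi estimators are
#' `dS = (L2 A2 + L4 A4) / (L2 + L4) + B4` and
#' `dN = A0 + (L0 B0 + L2 B2) / (L0 + L2)`.
#'
#' Codon columns containing a gap in either sequence are dropped pairwise;
#' codon pairs where either codon is a stop are excluded. Saturation (a log
#' argument <= 0) yields non-finite distances flagged in the result, not an
#' error; `dS = 0` flags the ratio as undefined (`NaN`, or `Inf` when
#' `dN > 0`).
#'
#' @param aligned_a,aligned_b Equal-length, in-frame aligned nucleotide
#'   strings (gap `-`).
#' @return List of class `dnds_result` with `L` (L0, L2, L4), `P`, `Q`,
#'   `A`, `B`, `dN`, `dS`, `dnds`, `saturated`, `ratio_defined`.
#' @export
li93_dnds <- function(aligned_a, aligned_b) {
  a <- toupper(aligned_a); b <- toupper(aligned_b)
  if (nchar(a) != nchar(b)) stop("li93_dnds: alignment lengths differ")
  n <- nchar(a)
  if (n %% 3 != 0) stop("li93_dnds: alignment length not divisible by 3")
  st <- seq(1, n, 3)
  cod_a <- substring(a, st, st + 2); cod_b <- substring(b, st, st + 2)
  keep <- !grepl("-", cod_a, fixed = TRUE) & !grepl("-", cod_b, fixed = TRUE) &
    !(cod_a %in% .STOP_CODONS) & !(cod_b %in% .STOP_CODONS) &
    !grepl("[^ACGT]", cod_a) & !grepl("[^ACGT]", cod_b)
  cod_a <- cod_a[keep]; cod_b <- cod_b[keep]
  if (length(cod_a) == 0) stop("li93_dnds: no usable codon columns")
  tab <- .degeneracy_table()
  cls <- c("0" = 1L, "2" = 2L, "4" = 3L)
  L <- c(0, 0, 0); TS <- c(0, 0, 0); TV <- c(0, 0, 0)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (i in seq_along(cod_a)) {
    da <- tab[cod_a[i], ]; db <- tab[cod_b[i], ]
    ia <- cls[as.character(da)]; ib <- cls[as.character(db)]
    for (p in 1:3) {
      L[ia[p]] <- L[ia[p]] + 0.5
      L[ib[p]] <- L[ib[p]] + 0.5
      x <- substr(cod_a[i], p, p); y <- substr(cod_b[i], p, p)
      if (x != y) {
        w <- if (purine[x] == purine[y]) "ts" else "tv"
        if (w == "ts") {
          TS[ia[p]] <- TS[ia[p]] + 0.5; TS[ib[p]] <- TS[ib[p]] + 0.5
        } else {
          TV[ia[p]] <- TV[ia[p]] + 0.5; TV[ib[p]] <- TV[ib[p]] + 0.5
        }
      }
    }
  }
  P <- ifelse(L > 0, TS / L, 0)
  Q <- ifelse(L > 0, TV / L, 0)
  # log arguments go non-positive at saturation; the NaN is the flag
  A <- suppressWarnings(-0.5 * log(1 - 2 * P - Q) + 0.25 * log(1 - 2 * Q))
  B <- suppressWarnings(-0.5 * log(1 - 2 * Q))
  saturated <- any(!is.finite(A)) || any(!is.finite(B))
  dS <- (L[2] * A[2] + L[3] * A[3]) / (L[2] + L[3]) + B[3]
  dN <- A[1] + (L[1] * B[1] + L[2] * B[2]) / (L[1] + L[2])
  ratio_defined <- is.finite(dS) && dS > 0 && is.finite(dN)
  dnds <- if (ratio_defined) dN / dS else if (isTRUE(dN > 0) && isTRUE(dS == 0))
    Inf else NaN
  structure(list(
    L = stats::setNames(L, c("L0", "L2", "L4")),
    P = stats::setNames(P, c("P0", "P2", "P4")),
    Q = stats::setNames(Q, c("Q0", "Q2", "Q4")),
    A = stats::setNames(A, c("A0", "A2", "A4")),
    B = stats::setNames(B, c("B0", "B2", "B4")),
    dN = dN, dS = dS, dnds = dnds,
    saturated = saturated, ratio_defined = ratio_defined),
    class = "dnds_result")
}

#' Percent nucleotide identity of an alignment
#'
#' Identical columns over columns without a gap in either sequence, as a
#' percentage; gap columns are excluded from the denominator.
#'
#' @param aligned_a,aligned_b Equal-length aligned strings.
#' @return Percent identity.
#' @export
nt_identity <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("nt_identity: alignment lengths differ")
  a <- strsplit(toupper(aligned_a), NULL)[[1]]
  b <- strsplit(toupper(aligned_b), NULL)[[1]]
  nongap <- a != "-" & b != "-"
  if (!any(nongap)) stop("nt_identity: no non-gap columns")
  100 * sum(a[nongap] == b[nongap]) / sum(nongap)
}
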