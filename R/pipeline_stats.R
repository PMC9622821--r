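#' Representation factor of the overlap between two gene sets
#'
#' The expected overlap of two sets of sizes `n1` and `n2` drawn from a
#' universe of `N` genes is `n1 * n2 / N`; the representation factor is
#' observed / expected (1 = random expectation, > 1 enrichment, < 1
#' depletion). Significance is assessed with hypergeometric tails:
#' enrichment `P(X >= observed)` and depletion `P(X <= observed)`, both
#' reported.
#'
#' @param observed Observed overlap (0 <= observed <= min(n1, n2)).
#' @param n1,n2 Group sizes.
#' @param N Universe size (>= n1, n2; > 0).
#' @return List of class `overlap_stats`: `n1`, `n2`, `N`, `observed`,
#'   `expected`, `representation_factor`, `p_enrichment`, `p_depletion`.
#' @export
representation_factor <- function(observed, n1, n2, N) {
  if (N <= 0 || n1 <= 0 || n2 <= 0)
    stop("representation_factor: empty group or universe")
  if (n1 > N || n2 > N || observed > min(n1, n2) || observed < 0)
    stop("representation_factor: inconsistent counts")
  expected <- n1 * n2 / N
  structure(list(
    n1 = n1, n2 = n2, N = N, observed = observed, expected = expected,
    representation_factor = observed / expected,
    p_enrichment = stats::phyper(observed - 1, n1, N - n1, n2,
                                 lower.tail = FALSE),
    p_depletion = stats::phyper(observed, n1, N - n1, n2)),
    class = "overlap_stats")
}

#' Poisson test of ribo-bound ORF clustering within transcripts
#'
#' Under independent assortment, the number of ribo-bound ORFs per
#' transcript follows a Poisson distribution with mean `lambda` equal to the
#' overall average. Observed counts are compared to the Poisson expectation
#' (upper bin pooled at the maximum observed count) with a chi-square
#' goodness-of-fit test; bins are pooled from the right until every expected
#' count is >= 5, and one degree of freedom is spent on the estimated
#' `lambda`. Excess mass at high counts signals clustering of ribosome
#' binding in particular transcripts.
#'
#' @param bound_counts_per_transcript Integer vector: ribo-bound ORFs per
#'   transcript (one entry per transcript, zeros included).
#' @return List of class `clustering_result`: `lambda`, `observed` and
#'   `expected` histograms over k, `pooled` (data.frame of test bins),
#'   `statistic`, `df`, `p_value` (NA when fewer than 2 usable bins).
#' @export
poisson_clustering <- function(bound_counts_per_transcript) {
  x <- bound_counts_per_transcript
  if (length(x) < 1) stop("poisson_clustering: need at least one transcript")
  n <- length(x)
  lambda <- mean(x)
  kmax <- max(x)
  k <- 0:kmax
  observed <- as.numeric(table(factor(x, levels = k)))
  expected <- n * stats::dpois(k, lambda)
  expected[length(expected)] <- n * stats::ppois(kmax - 1, lambda,
                                                 lower.tail = FALSE)
  # pool from the right until all expected bins >= 5
  obs_p <- observed; exp_p <- expected; lab <- as.character(k)
  while (length(exp_p) > 1 && exp_p[length(exp_p)] < 5) {
    m <- length(exp_p)
    exp_p[m - 1] <- exp_p[m - 1] + exp_p[m]
    obs_p[m - 1] <- obs_p[m - 1] + obs_p[m]
    lab[m - 1] <- paste0(">=", sub(">=", "", lab[m - 1]))
    exp_p <- exp_p[-m]; obs_p <- obs_p[-m]; lab <- lab[-m]
  }
  if (length(exp_p) >= 3 && all(exp_p > 0)) {
    statistic <- sum((obs_p - exp_p)^2 / exp_p)
    df <- length(exp_p) - 2
    p_value <- stats::pchisq(statistic, df, lower.tail = FALSE)
  } else {
    statistic <- NA_real_; df <- NA_integer_; p_value <- NA_real_
  }
  structure(list(lambda = lambda,
                 observed = stats::setNames(observed, k),
                 expected = stats::setNames(expected, k),
                 pooled = data.frame(bin = lab, observed = obs_p,
                                     expected = exp_p),
                 statistic = statistic, df = df, p_value = p_value),
            class = "clustering_result")
}
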