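# Shared hypergeometric kernel. Every enrichment-style statistic in the
# package (miRNA/mRNA over-targeting, gene-set enrichment, DE-in-module
# enrichment, module overlap) calls this single function, so their p-values
# are numerically identical for identical counts.

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' X counts the successes in \code{K} draws without replacement from a
#' population of size \code{N} containing \code{n} successes.
#'
#' @param k observed overlap (vectorized).
#' @param N population size.
#' @param K number of draws.
#' @param n number of successes in the population.
#' @return P(X >= k); equals 1 when \code{k <= 0}.
#' @export
hyperTailP <- function(k, N, K, n) {
  if (any(N < 0) || any(K > N) || any(n > N) || any(K < 0) || any(n < 0))
    stop("invalid hypergeometric counts: need 0 <= K, n <= N")
  if (any(k > pmin(K, n)))
    stop("overlap k cannot exceed min(K, n)")
  phyper(k - 1, m = n, n = N - n, k = K, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Adjusted values are clipped to 1 and monotone in p-rank; ties and input
#' order are handled as by the standard step-up procedure.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return vector of BH-adjusted p-values, same length and order as input.
#' @export
bhAdjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Pearson goodness-of-fit test of an observed proportion
#'
#' One-sample chi-squared test (df = 1, no continuity correction) of the
#' split (\code{k}, \code{n - k}) against expected proportions
#' (\code{p0}, \code{1 - p0}); the p-value is two-sided.
#'
#' @param k observed successes.
#' @param n total trials.
#' @param p0 expected success proportion, in (0, 1).
#' @return list with \code{chi2} and \code{p}.
#' @export
proportionGofTest <- function(k, n, p0) {
  if (n <= 0) stop("n must be > 0")
  if (k < 0 || k > n) stop("k must lie in 0..n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  e <- c(n * p0, n * (1 - p0))
  o <- c(k, n - k)
  chi2 <- sum((o - e)^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}
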