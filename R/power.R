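#' Power of a robust Wald test from a RESI via the non-central F distribution
#'
#' For an association with standardized effect size `S` tested on `m`
#' parameter(s) in a model with `df_model` total degrees of freedom, the test
#' statistic at sample size `N` is approximately non-central F with
#' `df1 = m`, `df2 = N - df_model` and non-centrality `lambda = N * S^2`.
#' Power is the probability that this statistic exceeds the central-F
#' critical value at level `alpha`. With `m = 1` this is the standard
#' single-parameter calculation; larger `m` generalizes it to joint (e.g.
#' spline) tests.
#'
#' @param S standardized effect size (RESI), >= 0.
#' @param N sample size (subjects); must exceed `df_model + 1`.
#' @param df_model total degrees of freedom of the analysis model.
#' @param m number of tested parameters (default 1).
#' @param alpha significance level (default 0.05).
#' @return power in (0, 1); exactly `alpha` when `S = 0`.
#' @export
power_ncf <- function(S, N, df_model = 2, m = 1, alpha = 0.05) {
  stopifnot(S >= 0, alpha > 0, alpha < 1, m >= 1)
  if (any(N <= df_model + 1))
    stop("N must exceed df_model + 1")
  df2 <- N - df_model
  crit <- stats::qf(1 - alpha, m, df2)
  stats::pf(crit, m, df2, ncp = N * S^2, lower.tail = FALSE)
}

#' Replicability of a result with known power
#'
#' Replicability is the probability that two independent, identically
#' designed studies both reject the null — the square of the power.
#'
#' @param p power value(s) in [0, 1].
#' @return `p^2`.
#' @export
replicability_from_power <- function(p) {
  if (any(p < 0 | p > 1)) stop("power must be in [0, 1]")
  p^2
}

#' Smallest sample size reaching a target power or replicability
#'
#' Solves `N* = min{N : power(N) >= gamma}` for the non-central F power of
#' [power_ncf()], by monotone bracketing (power is strictly increasing in
#' `N`) followed by integer bisection; the returned `N*` satisfies
#' `power(N*) >= gamma > power(N* - 1)`. `n_for_replicability(r)` converts
#' the target via `gamma = sqrt(r)` and is exactly
#' `n_for_power(sqrt(r))`.
#'
#' @param S standardized effect size (RESI), > 0.
#' @param gamma target power in (0, 1).
#' @param r target replicability in (0, 1).
#' @param df_model,m,alpha as in [power_ncf()].
#' @return smallest integer sample size meeting the target.
#' @export
n_for_power <- function(S, gamma, df_model = 2, m = 1, alpha = 0.05) {
  if (S <= 0)
    stop("target unattainable: S must be > 0 to reach power above alpha")
  stopifnot(gamma > 0, gamma < 1)
  lo <- df_model + 2L
  if (power_ncf(S, lo, df_model, m, alpha) >= gamma) return(lo)
  hi <- lo
  repeat {
    hi <- hi * 2L
    if (power_ncf(S, hi, df_model, m, alpha) >= gamma) break
    if (hi > 1e9) stop("sample size search exceeded 1e9")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (power_ncf(S, mid, df_model, m, alpha) >= gamma) hi <- mid else lo <- mid
  }
  hi
}

#' @rdname n_for_power
#' @export
n_for_replicability <- function(S, r, df_model = 2, m = 1, alpha = 0.05) {
  stopifnot(r > 0, r < 1)
  n_for_power(S, sqrt(r), df_model, m, alpha)
}

#' Empirical power from replicate p-values
#'
#' The proportion of bootstrap replicates with `p <= alpha`, plus the implied
#' replicability (the proportion squared).
#'
#' @param pvalues non-empty numeric vector of replicate p-values (`NA`s from
#'   failed replicates are dropped).
#' @param alpha significance level (default 0.05).
#' @return list with `estimate` (= k/n), `k`, `n` and `replicability`.
#' @export
empirical_power <- function(pvalues, alpha = 0.05) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("empty p-value vector")
  k <- sum(pvalues <= alpha)
  n <- length(pvalues)
  list(estimate = k / n, k = k, n = n, replicability = (k / n)^2)
}

#' Wilson score interval for a binomial proportion
#'
#' The score-based interval: with `z` the standard-normal quantile for the
#' chosen level and `p = k/n`,
#' \deqn{\frac{p + z^2/2n \pm z \sqrt{p(1-p)/n + z^2/4n^2}}{1 + z^2/n}.}
#' Unlike the Wald interval it never leaves [0, 1] and behaves well at the
#' boundaries: `k = 0` gives a lower bound of 0 and `k = n` an upper bound
#' of 1.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
wilson_interval <- function(k, n, level = 0.95) {
  if (k > n || k < 0) stop("k must be in [0, n]")
  stopifnot(n >= 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(low = max(0, centre - half), high = min(1, centre + half))
}
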