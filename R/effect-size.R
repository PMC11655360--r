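#' Robust effect size index (RESI) point estimate
#'
#' Converts a robust Wald chi-squared statistic into the RESI estimate
#' \deqn{\hat S = \sqrt{\max\{0, (T^2 - m)/N\}}}
#' where `m` is the number of tested parameters and `N` the number of
#' participants (subjects, not observations, in longitudinal fits). The
#' subtraction of `m` removes the statistic's null expectation; truncation at
#' zero keeps the estimate on the effect-size scale.
#'
#' @param T2 chi-squared Wald statistic (>= 0).
#' @param m number of tested parameters (>= 1).
#' @param N number of participants (> 0).
#' @return non-negative RESI estimate.
#' @export
resi_point <- function(T2, m, N) {
  if (N <= 0) stop("N must be positive")
  stopifnot(m >= 1, T2 >= 0)
  sqrt(pmax(0, (T2 - m) / N))
}

#' RESI for terms of a fitted association model
#'
#' Runs [wald_test()] on the named terms and converts the statistic with
#' [resi_point()], using `N =` the fit's subject count — duplicating every
#' subject's rows leaves the estimate's `N` unchanged.
#'
#' @param fit a `study_fit` from [fit_study_model()].
#' @param terms term labels to test jointly.
#' @return an `effect_size_estimate`: `S_hat`, `m`, `n_subjects`, `T2`, `p`,
#'   variant `"RESI"`; CI fields are `NA` until filled by a bootstrap.
#' @export
resi_for_terms <- function(fit, terms) {
  wt <- wald_test(fit, terms)
  new_effect_size(S_hat = resi_point(wt$T2, wt$m, fit$n_subjects),
                  m = wt$m, n_subjects = fit$n_subjects, T2 = wt$T2,
                  p = wt$p, variant = "RESI")
}

new_effect_size <- function(S_hat, m, n_subjects, T2, p = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            ci_level = NA_real_, n_boot = 0L,
                            variant = "RESI") {
  structure(list(S_hat = S_hat, m = m, n_subjects = n_subjects, T2 = T2,
                 p = p, ci_low = ci_low, ci_high = ci_high,
                 ci_level = ci_level, n_boot = n_boot, variant = variant),
            class = "effect_size_estimate")
}

#' @export
print.effect_size_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f (N = %d, m = %d, T2 = %.3f)\n",
              x$variant, x$S_hat, x$n_subjects, x$m, x$T2))
  if (!is.na(x$ci_low))
    cat(sprintf("%.0f%% percentile bootstrap CI [%.4f, %.4f] (%d replicates)\n",
                100 * x$ci_level, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Percentile bootstrap confidence interval for the RESI
#'
#' Non-parametric subject-level bootstrap: whole subjects are resampled with
#' replacement (all their visits travel together, preserving the
#' within-subject correlation), the model is refitted and the RESI
#' recomputed for each replicate. The interval is the percentile interval of
#' the replicate estimates — for `level = 0.95` and `n_boot = 1000` the lower
#' and upper 2.5% quantiles. The point estimate comes from the full table.
#' Replicates whose fit fails are excluded with a recorded count, never
#' silently retried.
#'
#' @param table a cohort table.
#' @param formula model formula (see [fit_study_model()]).
#' @param terms term labels to test.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; per-replicate seeds are derived from it.
#' @param design,weights passed to [fit_study_model()].
#' @return an `effect_size_estimate` with CI fields and `n_failed` attribute.
#' @export
bootstrap_resi_ci <- function(table, formula, terms, n_boot = 1000L,
                              level = 0.95, seed = 1L, design = NULL,
                              weights = NULL) {
  stopifnot(n_boot >= 2L)
  design <- design %||% cohort_design(table)
  full <- fit_study_model(table, formula, design = design, weights = weights)
  est <- resi_for_terms(full, terms)

  seeds <- derive_seeds(seed, n_boot)
  subj <- unique(table$subject_id)
  rows_of <- split(seq_len(nrow(table)), table$subject_id)[as.character(subj)]
  S_boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    pick <- with_seed(seeds[b],
                      sample.int(length(subj), replace = TRUE))
    idx <- unlist(rows_of[pick], use.names = FALSE)
    bt <- table[idx, , drop = FALSE]
    # relabel so resampled copies of a subject stay distinct clusters
    bt$subject_id <- rep(seq_along(pick), lengths(rows_of[pick]))
    S_boot[b] <- tryCatch({
      f <- fit_study_model(bt, formula, design = design, weights = weights)
      resi_for_terms(f, terms)$S_hat
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(S_boot)
  if (!any(ok)) stop("all bootstrap replicate fits failed")
  probs <- round(c((1 - level) / 2, 1 - (1 - level) / 2), 10)
  qs <- stats::quantile(S_boot[ok], probs, type = 1, names = FALSE)
  out <- new_effect_size(S_hat = est$S_hat, m = est$m,
                         n_subjects = est$n_subjects, T2 = est$T2, p = est$p,
                         ci_low = qs[1], ci_high = qs[2], ci_level = level,
                         n_boot = sum(ok), variant = "RESI")
  attr(out, "n_failed") <- sum(!ok)
  attr(out, "S_boot") <- S_boot[ok]
  out
}

#' Convert between Cohen's d and RESI
#'
#' For a two-group mean comparison under Cohen's assumptions (equal
#' variances, balanced allocation) the RESI equals half of Cohen's d, so
#' Cohen's thresholds map to RESI 0.1 (small), 0.25 (medium) and 0.4
#' (large). Unlike the pooled-SD d, the RESI stays consistent when group
#' variances differ.
#'
#' @param d Cohen's d value(s).
#' @param S RESI value(s), >= 0.
#' @return the converted effect size(s).
#' @export
d_to_resi <- function(d) d / 2

#' @rdname d_to_resi
#' @export
resi_to_d <- function(S) {
  if (any(S < 0)) stop("S must be >= 0")
  2 * S
}

#' Cross-sectional-equivalent RESI (CS-RESI) for longitudinal data
#'
#' Estimates the RESI the same study population would have produced had the
#' study been conducted cross-sectionally: repeatedly draw one visit per
#' subject at random, fit the cross-sectional model on each one-visit
#' subsample, compute its RESI, and average over subsamples. Because a
#' longitudinal design typically extracts more information per subject, the
#' CS-RESI is usually smaller than the longitudinal RESI for the same
#' association. The confidence interval is a subject-level percentile
#' bootstrap of the whole subsample-averaged estimator.
#'
#' @param table a longitudinal cohort table (cross-sectional input is
#'   redirected to [resi_for_terms()]).
#' @param formula model formula for the cross-sectional fit.
#' @param terms term labels to test.
#' @param n_subsamples one-visit-per-subject subsamples averaged per
#'   estimate (default 20).
#' @param n_boot bootstrap replicates for the CI; 0 skips the CI.
#' @param seed integer seed.
#' @return an `effect_size_estimate` with variant `"CS-RESI"`.
#' @export
cs_resi <- function(table, formula, terms, n_subsamples = 20L, n_boot = 0L,
                    seed = 1L) {
  if (cohort_design(table) == "cross-sectional")
    stop("table is cross-sectional; use resi_for_terms() on a ",
         "cross-sectional fit directly")
  seeds <- derive_seeds(seed, 2L)

  point <- cs_resi_point(table, formula, terms, n_subsamples, seeds[1])

  ci_low <- ci_high <- NA_real_
  n_ok <- 0L
  if (n_boot > 0L) {
    bseeds <- derive_seeds(seeds[2], n_boot)
    subj <- unique(table$subject_id)
    rows_of <- split(seq_len(nrow(table)), table$subject_id)[as.character(subj)]
    S_boot <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      pick <- with_seed(bseeds[b],
                        sample.int(length(subj), replace = TRUE))
      idx <- unlist(rows_of[pick], use.names = FALSE)
      bt <- table[idx, , drop = FALSE]
      bt$subject_id <- rep(seq_along(pick), lengths(rows_of[pick]))
      S_boot[b] <- tryCatch(
        cs_resi_point(bt, formula, terms, n_subsamples, bseeds[b])$S_hat,
        error = function(e) NA_real_)
    }
    ok <- !is.na(S_boot)
    n_ok <- sum(ok)
    if (n_ok >= 2L) {
      qs <- stats::quantile(S_boot[ok], c(0.025, 0.975), type = 1,
                            names = FALSE)
      ci_low <- qs[1]; ci_high <- qs[2]
    }
  }
  new_effect_size(S_hat = point$S_hat, m = point$m,
                  n_subjects = point$n_subjects, T2 = point$T2,
                  ci_low = ci_low, ci_high = ci_high,
                  ci_level = if (n_boot > 0) 0.95 else NA_real_,
                  n_boot = n_ok, variant = "CS-RESI")
}

## average cross-sectional RESI over one-visit-per-subject subsamples
cs_resi_point <- function(table, formula, terms, n_subsamples, seed) {
  sseeds <- derive_seeds(seed, n_subsamples)
  rows_of <- split(seq_len(nrow(table)), table$subject_id)
  S <- T2 <- rep(NA_real_, n_subsamples)
  m <- N <- NA_integer_
  for (k in seq_len(n_subsamples)) {
    idx <- with_seed(sseeds[k], vapply(rows_of, function(r)
      if (length(r) == 1L) r else r[sample.int(length(r), 1L)], integer(1)))
    sub <- table[idx, , drop = FALSE]
    fit <- fit_study_model(sub, formula, design = "cross-sectional")
    wt <- wald_test(fit, terms)
    S[k] <- resi_point(wt$T2, wt$m, fit$n_subjects)
    T2[k] <- wt$T2; m <- wt$m; N <- fit$n_subjects
  }
  list(S_hat = mean(S), T2 = mean(T2), m = m, n_subjects = N)
}
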