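#' Summarize a study's design features
#'
#' Computes the design covariates used in effect-size meta-regression: mean,
#' SD and skewness of age, proportion of males, design type and subject
#' count. Age moments are computed over one record per subject — the baseline
#' row — so that a longitudinal study's feature set describes its enrolled
#' sample, not its visit schedule. Skewness is the adjusted Fisher–Pearson
#' sample skewness. The `< 3` longitudinal-subjects curation rule is applied
#' via [as_cohort_table()] semantics: such tables count as cross-sectional.
#'
#' @param table a non-empty cohort table.
#' @param study_id optional study label; defaults to the table's `study_id`
#'   column (first value) or `NA`.
#' @return one-row data.frame: `study_id`, `mean_age`, `sd_age`, `skew_age`,
#'   `prop_male`, `design`, `n_subjects`.
#' @export
summarize_design <- function(table, study_id = NULL) {
  stopifnot(nrow(table) > 0L)
  design <- cohort_design(table)
  base <- baseline_rows(table)
  data.frame(
    study_id = study_id %||%
      (if ("study_id" %in% names(table)) as.character(table$study_id[1])
       else NA_character_),
    mean_age = mean(base$age),
    sd_age = stats::sd(base$age),
    skew_age = sample_skewness(base$age),
    prop_male = mean(base$sex),
    design = design,
    n_subjects = nrow(base))
}

#' Meta-regression of study-level effect sizes on design features
#'
#' Weighted fixed-effect regression of per-study RESI estimates on design
#' features, with natural-spline (df = 3) terms for the continuous features
#' and an indicator for longitudinal design:
#'
#' * `model = "age"`:  `S_hat ~ design + ns(mean_age, 3) + ns(sd_age, 3) +
#'   ns(skew_age, 3)`
#' * `model = "sex"`:  `S_hat ~ design + ns(mean_age, 3) + ns(sd_age, 3) +
#'   ns(prop_male, 3)`
#'
#' Weights default to the inverse of each estimate's standard error (1/SE);
#' `weight_scheme = "inverse_variance"` switches to the conventional 1/SE^2.
#' Coefficient inference uses heteroskedasticity-robust (sandwich) standard
#' errors.
#'
#' @param studies data.frame with columns `study_id`, `S_hat`, `se` (> 0),
#'   `design`, `mean_age`, `sd_age`, `skew_age`, `prop_male`.
#' @param model `"age"` or `"sex"`.
#' @param weight_scheme `"inverse_se"` (default) or `"inverse_variance"`.
#' @param hc_type robust covariance flavour (`"HC0"` default, `"HC3"`).
#' @return a `meta_result`: `coefficients`, `robust_se`, `pvalues`,
#'   `fitted`, `residuals`, the underlying `lm` fit and the weights used.
#' @export
fit_meta_regression <- function(studies, model = c("age", "sex"),
                                weight_scheme = c("inverse_se",
                                                  "inverse_variance"),
                                hc_type = c("HC0", "HC3")) {
  model <- match.arg(model)
  weight_scheme <- match.arg(weight_scheme)
  hc_type <- match.arg(hc_type)
  req <- c("S_hat", "se", "design", "mean_age", "sd_age",
           if (model == "age") "skew_age" else "prop_male")
  miss <- setdiff(req, names(studies))
  if (length(miss))
    stop("studies table is missing: ", paste(miss, collapse = ", "))
  if (any(studies$se <= 0)) stop("all SEs must be > 0")

  f <- if (model == "age")
    S_hat ~ design + splines::ns(mean_age, 3) + splines::ns(sd_age, 3) +
      splines::ns(skew_age, 3)
  else
    S_hat ~ design + splines::ns(mean_age, 3) + splines::ns(sd_age, 3) +
      splines::ns(prop_male, 3)

  dat <- as.data.frame(studies)
  dat$design <- factor(dat$design,
                       levels = c("cross-sectional", "longitudinal"))
  p <- if (model == "age") 11L else 11L  # intercept + design + 3 splines x 3
  if (nrow(dat) < p + 2L)
    stop("need at least ", p + 2L, " studies to fit the ", model,
         " meta-model (", nrow(dat), " given)")
  w <- if (weight_scheme == "inverse_se") 1 / dat$se else 1 / dat$se^2
  dat$.w <- w
  fit <- stats::lm(f, data = dat, weights = .w)
  # suppressWarnings: bread.lm warns on perfect fits (constant effect sizes)
  V <- suppressWarnings(sandwich::vcovHC(fit, type = hc_type))
  se <- sqrt(diag(V))
  z <- stats::coef(fit) / se
  structure(list(coefficients = stats::coef(fit), robust_se = se,
                 pvalues = 2 * stats::pnorm(-abs(z)),
                 fitted = stats::fitted(fit),
                 residuals = stats::resid(fit),
                 model = model, weights = w, lm = fit,
                 feature_range = lapply(dat[intersect(
                   c("mean_age", "sd_age", "skew_age", "prop_male"),
                   names(dat))], range)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("effect-size meta-regression (%s model, %d studies)\n",
              x$model, length(x$fitted)))
  print(data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                   p = x$pvalues))
  invisible(x)
}

#' Partial prediction curve from a fitted meta-regression
#'
#' Predicts the expected standardized effect size while one design feature
#' varies over a grid and the others are held at reference values (defaults:
#' mean age 45 years, SD of age 7 years, skewness 0, proportion of males
#' 0.5, cross-sectional design). Grid points outside the observed feature
#' range trigger a warning — the spline is linear beyond its boundary knots,
#' so extrapolation is linear by construction.
#'
#' @param meta a `meta_result`.
#' @param vary feature to vary (`"mean_age"`, `"sd_age"`, `"skew_age"`,
#'   `"prop_male"`, or `NULL` for a single prediction at the reference
#'   point).
#' @param grid numeric grid for the varying feature.
#' @param fixed named list overriding the reference values.
#' @return data.frame with the grid and the predicted `S`.
#' @export
predict_partial <- function(meta, vary = NULL, grid = NULL, fixed = list()) {
  defaults <- list(mean_age = 45, sd_age = 7, skew_age = 0, prop_male = 0.5,
                   design = "cross-sectional")
  defaults[names(fixed)] <- fixed
  if (is.null(vary)) {
    nd <- as.data.frame(defaults)
    nd$design <- factor(nd$design,
                        levels = c("cross-sectional", "longitudinal"))
    return(data.frame(S = unname(stats::predict(meta$lm, newdata = nd))))
  }
  stopifnot(!is.null(grid))
  rng <- meta$feature_range[[vary]]
  if (!is.null(rng) && (min(grid) < rng[1] || max(grid) > rng[2]))
    warning("grid extends beyond the observed range of ", vary,
            "; spline extrapolation is linear")
  nd <- as.data.frame(defaults[setdiff(names(defaults), vary)])
  nd <- nd[rep(1L, length(grid)), , drop = FALSE]
  nd[[vary]] <- grid
  nd$design <- factor(nd$design,
                      levels = c("cross-sectional", "longitudinal"))
  out <- data.frame(grid, S = unname(stats::predict(meta$lm, newdata = nd)))
  names(out)[1] <- vary
  out
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across a family of tests (e.g.
#' one meta-regression per brain outcome). Validates the input range and
#' delegates to the standard step-up computation; the adjustment is
#' invariant to input order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
adjust_pvalues_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1] and non-missing")
  stats::p.adjust(pvalues, method = "BH")
}
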