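#' Natural cubic spline basis with quantile knot policies
#'
#' Wraps [splines::ns()] with the knot policies used for age effects
#' throughout this package: `df = 2` places one interior knot at the median
#' of `x`, `df = 3` places two interior knots at the tercile boundaries
#' (33rd/66th percentiles); boundary knots sit at the range of `x`, beyond
#' which the basis is linear. Other `df` values require explicit
#' `interior_knots`.
#'
#' @param x numeric vector.
#' @param df degrees of freedom (number of basis columns).
#' @param interior_knots optional explicit interior knots (overrides the
#'   quantile policy).
#' @param boundary_knots boundary knot pair; defaults to `range(x)`.
#' @return an `ns` basis matrix with `df` columns.
#' @export
natural_spline_basis <- function(x, df = 2, interior_knots = NULL,
                                 boundary_knots = range(x)) {
  if (length(unique(x)) < df + 2L)
    stop("x needs at least df + 2 distinct values for a df = ", df, " basis")
  if (is.null(interior_knots)) {
    if (!df %in% 2:3)
      stop("quantile knot policy is defined for df in {2, 3}; ",
           "supply interior_knots explicitly for df = ", df)
    probs <- seq(0, 1, length.out = df + 1L)[2:df]
    interior_knots <- unname(stats::quantile(x, probs))
  }
  splines::ns(x, knots = interior_knots, Boundary.knots = boundary_knots)
}

#' Fit a study-level association model
#'
#' Fits the package's study-level mean model — typically
#' `y ~ ns(age, df = 2) + sex (+ x)` — with design-appropriate machinery:
#' cross-sectional tables get ordinary least squares with a
#' heteroskedasticity-robust (sandwich) covariance; longitudinal tables get a
#' GEE with identity link, exchangeable working correlation and a
#' subject-clustered sandwich covariance. Rows with missing values in any
#' modelled column are dropped (the count is recorded in the result).
#'
#' @param table a cohort table.
#' @param formula model formula; spline terms may use [splines::ns()] (e.g.
#'   `y ~ ns(age, df = 2) + sex`) or [natural_spline_basis()].
#' @param design `"cross-sectional"`, `"longitudinal"` or `NULL` to use the
#'   table's design.
#' @param weights optional name of a positive per-observation weight column
#'   (e.g. functional-connectivity frame counts).
#' @param hc_type sandwich flavour for cross-sectional fits: `"HC0"` (no
#'   small-sample correction, the default) or `"HC3"`.
#' @return a `study_fit` object: `beta_hat`, `robust_cov` (covariance of the
#'   coefficient estimates), `n_subjects`, `n_obs`, `df_model`, `term_index`
#'   (term -> coefficient positions), per-term Wald `pvalues`, and fit
#'   metadata.
#' @export
fit_study_model <- function(table, formula, design = NULL, weights = NULL,
                            hc_type = c("HC0", "HC3")) {
  hc_type <- match.arg(hc_type)
  design <- design %||% cohort_design(table)
  design <- match.arg(design, c("cross-sectional", "longitudinal"))

  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    stop("columns not present in table: ", paste(missing_cols, collapse = ", "))
  used <- unique(c(vars, "subject_id", weights))
  cc <- stats::complete.cases(table[intersect(used, names(table))])
  n_dropped <- sum(!cc)
  dat <- table[cc, , drop = FALSE]

  mf <- stats::model.frame(formula, dat)
  mt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(mt, mf)
  w <- if (!is.null(weights)) dat[[weights]] else NULL

  term_labels <- attr(mt, "term.labels")
  asg <- attr(X, "assign")
  term_index <- lapply(seq_along(term_labels), function(i) which(asg == i))
  names(term_index) <- term_labels

  if (design == "longitudinal") {
    if (!any(duplicated(dat$subject_id)))
      stop("longitudinal design requires repeated subjects")
    fit <- gee_fit(X, y, dat$subject_id, weights = w)
    beta <- fit$coefficients
    V <- fit$vcov
    extra <- list(alpha = fit$alpha, phi = fit$phi,
                  iterations = fit$iterations)
  } else {
    if (any(duplicated(dat$subject_id)))
      stop("cross-sectional design requires one row per subject")
    lmfit <- if (is.null(w)) stats::lm.fit(X, y) else
      stats::lm.wfit(X, y, w)
    if (lmfit$rank < ncol(X)) {
      bad <- colnames(X)[is.na(lmfit$coefficients)]
      stop("singular design matrix; collinear terms: ",
           paste(bad, collapse = ", "))
    }
    # route through lm() so sandwich::vcovHC handles weights/leverages
    dat_fit <- data.frame(.y = y, X[, -1L, drop = FALSE], check.names = FALSE)
    lmobj <- if (is.null(w)) stats::lm(.y ~ ., data = dat_fit) else
      stats::lm(.y ~ ., data = dat_fit, weights = w)
    beta <- stats::setNames(stats::coef(lmobj), colnames(X))
    # suppressWarnings: bread.lm warns on perfect fits (constant outcome)
    V <- unname(suppressWarnings(sandwich::vcovHC(lmobj, type = hc_type)))
    dimnames(V) <- list(colnames(X), colnames(X))
    extra <- list()
  }

  V <- (V + t(V)) / 2  # enforce symmetry against numerical drift
  pvals <- vapply(term_index, function(idx) {
    wald_stat(beta, V, idx)$p
  }, numeric(1))

  structure(c(list(beta_hat = beta, robust_cov = V,
                   n_subjects = length(unique(dat$subject_id)),
                   n_obs = nrow(dat), df_model = ncol(X),
                   term_index = term_index, pvalues = pvals,
                   formula = formula, design = design,
                   n_dropped = n_dropped, hc_type = hc_type),
              extra),
            class = "study_fit")
}

#' @export
print.study_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s\n", x$design, deparse(x$formula)))
  cat(sprintf("N = %d subjects, %d observations, df_model = %d\n",
              x$n_subjects, x$n_obs, x$df_model))
  print(data.frame(estimate = x$beta_hat,
                   robust_se = sqrt(diag(x$robust_cov))))
  invisible(x)
}

## Wald chi-squared for a coefficient subset against beta0
wald_stat <- function(beta, V, idx, beta0 = 0) {
  d <- beta[idx] - beta0
  m <- length(idx)
  # estimates exactly at the null (incl. degenerate zero-variance outcomes)
  if (all(abs(d) < 1e-12))
    return(list(T2 = 0, m = m, p = 1))
  T2 <- as.numeric(d %*% solve(V[idx, idx, drop = FALSE], d))
  list(T2 = max(T2, 0), m = m, p = stats::pchisq(max(T2, 0), m,
                                                 lower.tail = FALSE))
}

#' Robust Wald test of model terms
#'
#' Computes the chi-squared statistic `T^2 = (b - b0)' V^-1 (b - b0)` for the
#' coefficients belonging to the named terms, using the fit's robust
#' covariance `V`, with a chi-squared reference on `m` degrees of freedom
#' (`m` = number of tested coefficients; a df = 2 spline term contributes 2).
#'
#' @param fit a `study_fit`.
#' @param terms character vector of term labels (as in `fit$term_index`).
#' @param beta0 null value(s) for the tested coefficients (default 0).
#' @return list with `T2`, `m` and `p`.
#' @export
wald_test <- function(fit, terms, beta0 = 0) {
  unknown <- setdiff(terms, names(fit$term_index))
  if (length(unknown))
    stop("unknown term(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(fit$term_index), collapse = ", "))
  idx <- unlist(fit$term_index[terms], use.names = FALSE)
  wald_stat(fit$beta_hat, fit$robust_cov, idx, beta0)
}

#' Decompose a covariate into between- and within-subject effects
#'
#' Replaces a single longitudinal covariate effect with two terms: `X_bl`,
#' the subject's baseline covariate value (between-subject effect), and
#' `X_change`, the deviation of each visit's value from that baseline
#' (within-subject effect), fitted jointly by GEE alongside the adjustment
#' terms. Anchoring the between-subject term at baseline makes its
#' coefficient directly comparable to a baseline-only cross-sectional fit.
#' Subjects without a baseline row are excluded. Also returns the two design
#' variance components: the variance of the baseline covariate
#' (between-subject) and the mean square of `X_change` (within-subject).
#'
#' @param table a longitudinal cohort table.
#' @param covariate name of the covariate column to decompose.
#' @param adjust right-hand-side formula of adjustment terms, e.g.
#'   `~ ns(age, df = 2) + sex`; the default adjusts for age and sex.
#' @param outcome outcome column name (default `"y"`).
#' @param weights optional observation-weight column name.
#' @return a `between_within_fit`: `beta_between`, `beta_within`, robust SEs,
#'   `between_variance`, `within_variance`, and the underlying `study_fit`.
#' @export
fit_between_within <- function(table, covariate,
                               adjust = ~ ns(age, df = 2) + sex,
                               outcome = "y", weights = NULL) {
  if (cohort_design(table) != "longitudinal")
    stop("between/within decomposition requires a longitudinal table")
  base <- table[table$visit_index == 0L, , drop = FALSE]
  if (nrow(base) == 0L)
    stop("no baseline (visit_index == 0) rows in table")
  dat <- table[table$subject_id %in% base$subject_id, , drop = FALSE]
  xbl <- stats::setNames(base[[covariate]], as.character(base$subject_id))
  dat$X_bl <- xbl[as.character(dat$subject_id)]
  dat$X_change <- dat[[covariate]] - dat$X_bl
  if (all(abs(dat$X_change) < .Machine$double.eps * 100))
    stop("X_change is identically zero: no follow-up variation, ",
         "within-subject effect is undefined")

  rhs <- paste(c(deparse(adjust[[2]]), "X_bl", "X_change"), collapse = " + ")
  f <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- fit_study_model(dat, f, design = "longitudinal", weights = weights)

  ib <- fit$term_index[["X_bl"]]
  iw <- fit$term_index[["X_change"]]
  structure(list(
    beta_between = unname(fit$beta_hat[ib]),
    beta_within = unname(fit$beta_hat[iw]),
    se_between = sqrt(fit$robust_cov[ib, ib]),
    se_within = sqrt(fit$robust_cov[iw, iw]),
    between_variance = stats::var(dat$X_bl[dat$visit_index == 0L]),
    within_variance = mean(dat$X_change^2),
    fit = fit), class = "between_within_fit")
}

#' @export
print.between_within_fit <- function(x, ...) {
  cat("between/within covariate decomposition (GEE)\n")
  print(data.frame(
    effect = c("between (X_bl)", "within (X_change)"),
    estimate = c(x$beta_between, x$beta_within),
    robust_se = c(x$se_between, x$se_within),
    variance_component = c(x$between_variance, x$within_variance)))
  invisible(x)
}

#' Residualize outcomes for site main effects
#'
#' A location-only site adjustment: fits `outcome ~ covariates + site` by
#' least squares and subtracts each site's estimated main effect (centred at
#' the observation-weighted mean so the overall outcome level is preserved).
#' Conditioning on the covariates keeps covariate-outcome associations
#' intact; only additive between-site offsets are removed. With a single
#' site the table is returned unchanged.
#'
#' @param table a cohort table with a `site_id` column.
#' @param adjust right-hand-side formula of covariates to condition on.
#' @param outcomes outcome column names (default `"y"`).
#' @return the table with adjusted outcome columns.
#' @export
remove_site_effects <- function(table, adjust = ~ ns(age, df = 2) + sex,
                                outcomes = "y") {
  if (!"site_id" %in% names(table)) stop("site column 'site_id' is missing")
  site <- factor(table$site_id)
  if (nlevels(site) < 2L) return(table)
  Xadj <- stats::model.matrix(adjust, table)
  Msite <- stats::model.matrix(~ 0 + site)
  for (oc in outcomes) {
    fit <- stats::lm.fit(cbind(Xadj, Msite[, -1L, drop = FALSE]),
                         table[[oc]])
    gamma <- c(0, fit$coefficients[(ncol(Xadj) + 1L):length(fit$coefficients)])
    eff <- gamma[as.integer(site)]
    table[[oc]] <- table[[oc]] - (eff - mean(eff))
  }
  table
}
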