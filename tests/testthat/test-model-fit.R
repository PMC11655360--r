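test_that("spline knot policies place interior knots at the stated quantiles", {
  b2 <- natural_spline_basis(1:101, df = 2)
  expect_equal(unname(attr(b2, "knots")), 51)
  b3 <- natural_spline_basis(0:100, df = 3)
  expect_equal(unname(attr(b3, "knots")),
               unname(quantile(0:100, c(1/3, 2/3))))
  expect_equal(ncol(b2), 2L)
  expect_equal(ncol(b3), 3L)
})

test_that("natural splines reproduce any linear function exactly", {
  x <- sort(runif(80, 0, 10))
  b <- natural_spline_basis(x, df = 2)
  target <- 3 - 2 * x
  fit <- lm.fit(cbind(1, b), target)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("spline basis rejects degenerate inputs", {
  expect_error(natural_spline_basis(rep(1, 10), df = 2), "distinct")
  expect_error(natural_spline_basis(1:50, df = 4), "interior_knots")
  b4 <- natural_spline_basis(1:50, df = 4, interior_knots = c(15, 25, 35))
  expect_equal(ncol(b4), 4L)
})

test_that("cross-sectional fit recovers a known slope (closed-form OLS oracle)", {
  tab <- make_linear_table(2000, beta = 0.5, seed = 21)
  fit <- fit_study_model(tab, y ~ x, design = "cross-sectional")
  X <- cbind(1, tab$x)
  beta_ols <- solve(crossprod(X), crossprod(X, tab$y))
  expect_equal(unname(fit$beta_hat), as.vector(beta_ols), tolerance = 1e-10)
  expect_lt(abs(fit$beta_hat[["x"]] - 0.5), 3 * sqrt(fit$robust_cov[2, 2]))
})

test_that("constant outcome gives zero effects and a null Wald statistic", {
  tab <- make_linear_table(100, seed = 2)
  tab$y <- 7
  fit <- fit_study_model(tab, y ~ x, design = "cross-sectional")
  expect_equal(unname(fit$beta_hat[["x"]]), 0, tolerance = 1e-12)
  wt <- wald_test(fit, "x")
  expect_equal(wt$T2, 0)
  expect_equal(wt$p, 1)
})

test_that("GEE with one observation per cluster reproduces the LM fit", {
  tab <- make_linear_table(300, beta = 0.4, seed = 3)
  cs <- fit_study_model(tab, y ~ ns(age, df = 2) + sex + x,
                        design = "cross-sectional")
  X <- model.matrix(y ~ ns(age, df = 2) + sex + x, tab)
  ge <- bwasdesign:::gee_fit(X, tab$y, tab$subject_id)
  expect_equal(ge$coefficients, cs$beta_hat, tolerance = 1e-10)
  expect_equal(unname(ge$vcov), unname(cs$robust_cov), tolerance = 1e-8)
})

test_that("adding a constant to the outcome moves only the intercept", {
  tab <- make_longitudinal_fixture(n = 150, seed = 5)
  f1 <- fit_study_model(tab, y ~ ns(age, df = 2) + sex + x)
  tab2 <- tab; tab2$y <- tab2$y + 100
  f2 <- fit_study_model(tab2, y ~ ns(age, df = 2) + sex + x)
  expect_equal(f2$beta_hat[["(Intercept)"]] - f1$beta_hat[["(Intercept)"]],
               100, tolerance = 1e-8)
  expect_equal(f1$beta_hat[-1], f2$beta_hat[-1], tolerance = 1e-8)
})

test_that("singular designs fail with the collinear terms named", {
  tab <- make_linear_table(50, seed = 6)
  tab$x2 <- tab$x
  expect_error(fit_study_model(tab, y ~ x + x2, design = "cross-sectional"),
               "collinear")
  tabL <- make_longitudinal_fixture(n = 50, seed = 6)
  tabL$x2 <- tabL$x
  expect_error(fit_study_model(tabL, y ~ x + x2, design = "longitudinal"),
               "collinear")
})

test_that("rows with missing modelled values are dropped and counted", {
  tab <- make_linear_table(100, seed = 7)
  tab$x[c(3, 10)] <- NA
  fit <- fit_study_model(tab, y ~ x, design = "cross-sectional")
  expect_equal(fit$n_dropped, 2L)
  expect_equal(fit$n_obs, 98L)
})

test_that("GEE sandwich SEs track the empirical sampling SD", {
  # exchangeable correlation 0.5 via a subject intercept of equal variance
  reps <- 400
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    tab <- simulate_longitudinal_study(sim_config(
      n_subjects = 150, visits_per_subject = 3, beta_between = 0.3,
      beta_within = 0.3, subject_intercept_sd = 1, residual_sd = 1,
      seed = 5000 + r))
    fit <- fit_study_model(tab, y ~ x, design = "longitudinal")
    est[r] <- fit$beta_hat[["x"]]
    se[r] <- sqrt(fit$robust_cov["x", "x"])
  }
  expect_lt(abs(mean(se) / sd(est) - 1), 0.15)
})

test_that("working correlation estimate matches the generating ICC", {
  tab <- simulate_longitudinal_study(sim_config(
    n_subjects = 2000, visits_per_subject = 3, subject_intercept_sd = 1,
    residual_sd = 1, seed = 31))
  fit <- fit_study_model(tab, y ~ ns(age, df = 2) + sex + x)
  expect_lt(abs(fit$alpha - 0.5), 0.05)  # ICC = 1 / (1 + 1)
})

test_that("wald_test handles term bookkeeping and forced nulls", {
  tab <- make_longitudinal_fixture(n = 200, seed = 8)
  fit <- fit_study_model(tab, y ~ ns(age, df = 2) + sex + x)
  expect_error(wald_test(fit, "nope"), "unknown term")
  expect_equal(wald_test(fit, "ns(age, df = 2)")$m, 2L)
  forced <- wald_test(fit, "x", beta0 = fit$beta_hat[["x"]])
  expect_equal(forced$T2, 0)
  expect_equal(forced$p, 1)
})

test_that("robust covariance keeps size under heteroskedastic errors", {
  reps <- 1000
  n <- 500
  rej <- logical(reps)
  set.seed(99)
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    tab <- data.frame(subject_id = seq_len(n), visit_index = 0L, age = 50,
                      sex = 0L, x = x, y = rnorm(n, 0, 1 + abs(x)))
    fit <- fit_study_model(tab, y ~ x, design = "cross-sectional")
    rej[r] <- fit$pvalues[["x"]] <= 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("between/within decomposition recovers distinct effects", {
  reps <- 30
  bb <- bw <- numeric(reps)
  for (r in seq_len(reps)) {
    tab <- simulate_longitudinal_study(sim_config(
      n_subjects = 500, visits_per_subject = 2, beta_between = 0.3,
      beta_within = 0.3, covariate_within_sd = 0.7, seed = 700 + r))
    d <- fit_between_within(tab, "x")
    bb[r] <- d$beta_between; bw[r] <- d$beta_within
  }
  expect_lt(abs(mean(bb) - 0.3), 0.02)
  expect_lt(abs(mean(bw) - 0.3), 0.03)
})

test_that("variance components match their definitions", {
  tab <- make_longitudinal_fixture(n = 200, visits = 3, seed = 10)
  d <- fit_between_within(tab, "x")
  base <- tab[tab$visit_index == 0L, ]
  xbl <- setNames(base$x, base$subject_id)
  change <- tab$x - xbl[as.character(tab$subject_id)]
  expect_equal(d$between_variance, var(base$x))
  expect_equal(d$within_variance, mean(change^2))
})

test_that("decomposition rejects tables without follow-up variation", {
  tab <- make_linear_table(50, seed = 11)
  expect_error(fit_between_within(tab, "x"), "longitudinal")
  tabL <- make_longitudinal_fixture(n = 50, visits = 2, seed = 11)
  tabL$x <- ave(tabL$x, tabL$subject_id, FUN = function(v) v[1])
  expect_error(fit_between_within(tabL, "x"), "identically zero")
})

test_that("site residualization removes additive shifts exactly", {
  tab <- make_longitudinal_fixture(n = 300, seed = 12)
  shifted <- inject_site_effects(tab, site_config(5, 10, 0), seed = 3)
  adj <- remove_site_effects(shifted, adjust = ~ ns(age, df = 2) + sex + x)
  # covariate-adjusted residual site means vanish to numerical precision
  res <- lm(y ~ ns(age, df = 2) + sex + x, data = adj)$residuals
  site_means <- tapply(res, adj$site_id, mean)
  expect_lt(max(abs(site_means)), 1e-8)
  # adjusted outcome recovers the pre-shift association
  f0 <- fit_study_model(tab, y ~ ns(age, df = 2) + sex + x)
  f1 <- fit_study_model(adj, y ~ ns(age, df = 2) + sex + x)
  expect_equal(f1$beta_hat[["x"]], f0$beta_hat[["x"]], tolerance = 0.05)
})

test_that("site residualization is the identity for a single site", {
  tab <- make_longitudinal_fixture(n = 60, seed = 13)
  tab$site_id <- "site_1"
  expect_equal(remove_site_effects(tab)$y, tab$y)
  tab$site_id <- NULL
  expect_error(remove_site_effects(tab), "site")
})

test_that("no-op site adjustment leaves estimates within Monte-Carlo noise", {
  diffs <- vapply(1:25, function(r) {
    tab <- make_longitudinal_fixture(n = 200, seed = 900 + r)
    tab$site_id <- paste0("site_", sample(1:4, 200, replace = TRUE)[
      as.integer(factor(tab$subject_id))])
    adj <- remove_site_effects(tab, adjust = ~ ns(age, df = 2) + sex + x)
    f0 <- fit_study_model(tab, y ~ ns(age, df = 2) + sex + x)
    f1 <- fit_study_model(adj, y ~ ns(age, df = 2) + sex + x)
    f1$beta_hat[["x"]] - f0$beta_hat[["x"]]
  }, numeric(1))
  expect_lt(mean(abs(diffs)), 0.02)
})

test_that("single-effect GEE averages distinct between/within effects", {
  # beta_between = 0.6, beta_within = 0.1: the single-covariate estimate
  # must land inside [0.1, 0.6], and grow toward beta_within as the
  # within-subject covariate variance grows
  est_at <- function(wsd, seed) {
    tab <- simulate_longitudinal_study(sim_config(
      n_subjects = 1500, visits_per_subject = 3, beta_between = 0.6,
      beta_within = 0.1, covariate_between_sd = 1,
      covariate_within_sd = wsd, seed = seed))
    fit_study_model(tab, y ~ x)$beta_hat[["x"]]
  }
  lo <- mean(vapply(1:5, function(s) est_at(0.3, 40 + s), numeric(1)))
  hi <- mean(vapply(1:5, function(s) est_at(2.0, 50 + s), numeric(1)))
  expect_gt(lo, 0.1); expect_lt(lo, 0.6)
  expect_gt(hi, 0.1); expect_lt(hi, 0.6)
  expect_lt(hi, lo)  # more within-variance pulls toward beta_within
})

test_that("observation weights are honoured in both designs", {
  tab <- make_linear_table(400, beta = 0.5, seed = 14)
  tab$fc <- sample(50:300, 400, replace = TRUE)
  f_w <- fit_study_model(tab, y ~ x, design = "cross-sectional",
                         weights = "fc")
  w <- tab$fc; X <- cbind(1, tab$x)
  beta_wls <- solve(crossprod(X * sqrt(w)), crossprod(X * w, tab$y))
  expect_equal(unname(f_w$beta_hat), as.vector(beta_wls), tolerance = 1e-8)
})
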