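test_that("local frequencies count closed windows in up to three dimensions", {
  expect_equal(local_frequency(rep(3.2, 7)), rep(7L, 7))
  expect_equal(local_frequency(c(0, 2, 4, 6), halfwidth = 0.5), rep(1L, 4))
  # mixed 2-D case against the brute-force double loop
  set.seed(1)
  pts <- cbind(runif(200, 0, 5), runif(200, 0, 5))
  oracle <- vapply(seq_len(nrow(pts)), function(i)
    sum(abs(pts[, 1] - pts[i, 1]) <= 0.5 &
          abs(pts[, 2] - pts[i, 2]) <= 0.5), integer(1))
  expect_equal(local_frequency(pts, 0.5), oracle)
  expect_error(local_frequency(numeric(0)), "empty")
  expect_error(local_frequency(1:3, halfwidth = 0), "> 0")
})

test_that("uniform target on uniform data gives near-equal interior weights", {
  ages <- seq(50, 78, by = 0.25)
  wt <- cross_sectional_weights(ages, target_shape("uniform"),
                                winsor_bounds = c(50, 78))
  interior <- ages > 51 & ages < 77
  expect_lt(diff(range(wt$weight[interior])) / mean(wt$weight[interior]),
            1e-10)
})

test_that("winsorization affects weights only, never stored values", {
  ages <- c(40, seq(50, 78, by = 1))
  wt <- cross_sectional_weights(ages, target_shape("bell"),
                                winsor_bounds = c(50, 78))
  # the age-40 record is weighted as if it were 50
  expect_equal(wt$weight[1] * local_frequency(pmin(pmax(ages, 50), 78))[1],
               wt$weight[2] * local_frequency(pmin(pmax(ages, 50), 78))[2])
  expect_equal(ages[1], 40)  # input untouched
  expect_error(cross_sectional_weights(ages, target_shape("bell"),
                                       winsor_bounds = c(78, 50)),
               "inverted")
})

test_that("targeted resampling orders covariate variance U > uniform > bell", {
  set.seed(5)
  ages <- rnorm(800, 64, 6)
  shapes <- list(u_shaped = target_shape("u_shaped"),
                 uniform = target_shape("uniform"),
                 bell = target_shape("bell"))
  wts <- lapply(shapes, function(s)
    cross_sectional_weights(ages, s, winsor_bounds = c(50, 78)))
  tab <- data.frame(subject_id = seq_along(ages), visit_index = 0L,
                    age = ages, sex = 0L, y = 0)
  v <- vapply(wts, function(w) {
    mean(vapply(1:200, function(b)
      var(weighted_bootstrap(tab, w, 200, seed = b)$age), numeric(1)))
  }, numeric(1))
  expect_gt(v[["u_shaped"]], v[["uniform"]])
  expect_gt(v[["uniform"]], v[["bell"]])
})

test_that("binary weights hit the target class proportion", {
  vals <- rep(c(1L, 0L), c(1600, 400))  # prevalence exactly 0.8
  expect_equal(unique(binary_weights(vals, mean(vals))$weight), 1)
  wt <- binary_weights(vals, 0.5)
  ratio <- wt$weight[vals == 1][1] / wt$weight[vals == 0][1]
  expect_equal(ratio, (0.5 / 0.8) / (0.5 / 0.2))  # minority up by factor 4
  wt10 <- binary_weights(vals, 0.10)
  tab <- data.frame(subject_id = seq_along(vals), visit_index = 0L,
                    age = 50, sex = 0L, h = vals, y = 0)
  prev <- mean(vapply(1:300, function(b)
    mean(weighted_bootstrap(tab, wt10, 300, seed = b)$h), numeric(1)))
  expect_lt(abs(prev - 0.10), 0.01)
  expect_error(binary_weights(rep(1, 10), 0.5), "both classes")
  expect_error(binary_weights(vals, 1.2), "target_prop")
})

test_that("weighted bootstrap is deterministic and respects zero weights", {
  tab <- make_linear_table(100, seed = 3)
  wt <- cross_sectional_weights(tab$age, target_shape("uniform"))
  expect_identical(weighted_bootstrap(tab, wt, 40, seed = 5),
                   weighted_bootstrap(tab, wt, 40, seed = 5))
  wt$weight[1:50] <- 0
  bt <- weighted_bootstrap(tab, wt, 500, seed = 1)
  expect_true(all(bt$x %in% tab$x[51:100]))
  wt$weight[] <- 0
  expect_error(weighted_bootstrap(tab, wt, 10, seed = 1), "zero")
})

test_that("equal weights reduce to the ordinary bootstrap", {
  tab <- make_linear_table(50, seed = 4)
  wt <- cross_sectional_weights(tab$age, target_shape("uniform"))
  wt$weight[] <- 1
  counts <- table(factor(unlist(lapply(1:200, function(b)
    weighted_bootstrap(tab, wt, 50, seed = b)$x)), levels = tab$x))
  # each record's expected inclusion count is n / n_units = 1 per resample
  expect_lt(max(abs(as.vector(counts) / 200 - 1)), 0.35)
})

test_that("resampled ages converge to the target density", {
  set.seed(8)
  ages <- rnorm(2000, 64, 7)
  wt <- cross_sectional_weights(ages, target_shape("uniform"),
                                winsor_bounds = c(52, 76))
  tab <- data.frame(subject_id = seq_along(ages), visit_index = 0L,
                    age = ages, sex = 0L, y = 0)
  ks_at <- function(n) {
    draws <- unlist(lapply(1:5, function(b)
      weighted_bootstrap(tab, wt, n, seed = 80 + b)$age))
    draws <- draws[draws >= 52 & draws <= 76]
    suppressWarnings(ks.test(draws, "punif", 52, 76)$statistic)
  }
  expect_lt(ks_at(2000), ks_at(100))
  expect_lt(ks_at(2000), 0.05)
})

test_that("longitudinal combinations enumerate baseline-by-follow-up pairs", {
  tab <- simulate_longitudinal_study(sim_config(
    n_subjects = 40, visits_per_subject = 3, seed = 6))
  wt <- longitudinal_combination_weights(tab, target_shape("uniform"),
                                         target_shape("uniform"))
  expect_equal(nrow(wt), 40 * 2)  # 2 follow-ups -> 2 pairs per subject
  expect_equal(attr(wt, "unit"), "subject_pair")
  one <- tab[tab$subject_id == 1 & tab$visit_index <= 1, ]
  wt1 <- longitudinal_combination_weights(
    rbind(one, tab[tab$subject_id %in% 2:40, ]),
    target_shape("uniform"), target_shape("uniform"))
  expect_equal(sum(wt1$subject_id == 1), 1L)  # one follow-up -> one pair
  trip <- longitudinal_combination_weights(tab, target_shape("uniform"),
                                           target_shape("uniform"),
                                           n_followups = 2)
  expect_equal(attr(trip, "unit"), "subject_triple")
  expect_equal(nrow(trip), 40L)
})

test_that("pair bootstrap materializes two-visit subjects", {
  tab <- simulate_longitudinal_study(sim_config(
    n_subjects = 60, visits_per_subject = 3, seed = 7))
  wt <- longitudinal_combination_weights(tab, target_shape("uniform"),
                                         target_shape("uniform"))
  bt <- weighted_bootstrap(tab, wt, 30, seed = 2)
  expect_equal(nrow(bt), 60L)
  expect_equal(n_subjects(bt), 30L)
  expect_true(all(table(bt$subject_id) == 2))
  expect_true(all(tapply(bt$age, bt$subject_id, diff) > 0))
})

test_that("within-subject targets steer the resampled age gap", {
  tab <- simulate_longitudinal_study(sim_config(
    n_subjects = 400, visits_per_subject = 3,
    visit_gap_distribution = list(dist = "uniform", min = 0.3, max = 4),
    seed = 8))
  gap_for <- function(shape) {
    wt <- longitudinal_combination_weights(tab, target_shape("uniform"),
                                           target_shape(shape),
                                           winsor_within = c(0, 5))
    mean(vapply(1:100, function(b) {
      bt <- weighted_bootstrap(tab, wt, 100, seed = 300 + b)
      mean(tapply(bt$age, bt$subject_id, function(a) diff(range(a))))
    }, numeric(1)))
  }
  g_inc <- gap_for("increasing"); g_dec <- gap_for("decreasing")
  expect_gt(g_inc, g_dec)
})

test_that("between and within targets act independently", {
  # winsor bounds trim only tails here: bounds that clamp a large share of
  # records create a frequency mass point and distort the joint weighting
  tab <- simulate_longitudinal_study(sim_config(
    n_subjects = 600, visits_per_subject = 3,
    baseline_age_distribution = list(dist = "uniform", min = 55, max = 75),
    visit_gap_distribution = list(dist = "uniform", min = 0.5, max = 2.5),
    seed = 9))
  stats_for <- function(within_shape) {
    wt <- longitudinal_combination_weights(tab, target_shape("u_shaped"),
                                           target_shape(within_shape),
                                           winsor_within = c(0, 5))
    b <- tab$age[wt$row_baseline]
    ch <- tab$age[wt$row_f1] - b
    c(base = weighted.mean(b, wt$weight),
      change = weighted.mean(ch, wt$weight))
  }
  inc <- stats_for("increasing"); dec <- stats_for("decreasing")
  # the within shape moves the change distribution ...
  expect_gt(inc[["change"]] - dec[["change"]], 0.5)
  # ... but leaves the baseline-age distribution unchanged in expectation
  expect_lt(abs(inc[["base"]] - dec[["base"]]), 0.3)
})

test_that("scheme experiments are reproducible and summarize replicates", {
  tab <- make_linear_table(300, beta = 0.5, seed = 10)
  wt <- cross_sectional_weights(tab$age, target_shape("uniform"))
  e1 <- run_scheme_experiment(tab, list(unif = wt), n_grid = c(50, 100),
                              B = 1, formula = y ~ x, terms = "x", seed = 4)
  e2 <- run_scheme_experiment(tab, list(unif = wt), n_grid = c(50, 100),
                              B = 1, formula = y ~ x, terms = "x", seed = 4)
  expect_identical(e1$replicates$S, e2$replicates$S)
  e <- run_scheme_experiment(tab, list(unif = wt), n_grid = 80, B = 20,
                             formula = y ~ x, terms = "x", seed = 5)
  expect_equal(nrow(e$summary), 1L)
  expect_equal(e$summary$n_failed, 0L)
  expect_equal(e$summary$mean_S,
               mean(e$replicates$S), tolerance = 1e-12)
  expect_error(run_scheme_experiment(tab, list(wt), 50, 2, y ~ x, "x"),
               "named")
})
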