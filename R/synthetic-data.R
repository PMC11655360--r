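#' Simulation configuration for a single cohort
#'
#' Bundles the data-generating parameters for one synthetic study. The
#' generating mean model mirrors the association models fitted downstream:
#'
#' \deqn{y_{ij} = \mu + f(age_{ij}) + \beta_{sex} sex_i + \beta_b b_i +
#'   \beta_w w_{ij} + u_i + e_{ij}}
#'
#' where `b_i` is the subject-level covariate component (SD
#' `covariate_between_sd`), `w_ij` the visit-level deviation (SD
#' `covariate_within_sd`), `u_i` a subject random intercept and `e_ij`
#' Gaussian residual noise. The observed covariate is `x = b + w`. The age
#' effect `f` is a cubic polynomial on standardized age with coefficients
#' `age_effect`, a smooth non-linearity that a df=2 natural-spline fit can
#' track.
#'
#' @param n_subjects number of subjects (positive integer).
#' @param visits_per_subject visits per subject (integer >= 1); 1 yields a
#'   cross-sectional table.
#' @param baseline_age_distribution named distribution for baseline age in
#'   years: `list(dist = "normal"|"uniform"|"gamma", ...)` with parameters
#'   `mean`/`sd` (normal), `min`/`max` (uniform) or `shape`/`rate`/`shift`
#'   (gamma; `shift` locates the left end, producing right-skewed ages).
#' @param visit_gap_distribution distribution for the (non-negative) gap in
#'   years between consecutive visits: `list(dist = "uniform", min, max)` or
#'   `list(dist = "exponential", rate)` plus optional `min` floor.
#' @param beta_between,beta_within between- and within-subject covariate
#'   effects (outcome units per covariate unit).
#' @param age_effect length-3 numeric: coefficients of the linear, quadratic
#'   and cubic terms of standardized age.
#' @param sex_effect outcome shift for sex = 1.
#' @param sex_prob probability of sex = 1.
#' @param subject_intercept_sd SD of the subject random intercept (>= 0).
#' @param residual_sd residual SD (> 0).
#' @param covariate_between_sd,covariate_within_sd SDs of the covariate's
#'   subject-level component and visit-level deviation (>= 0).
#' @param missing_rate probability in [0, 1) that a non-baseline visit is
#'   dropped; baseline visits are never dropped so baseline-anchored models
#'   stay estimable.
#' @param seed integer seed; the same config and seed always reproduce the
#'   same table.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects,
                       visits_per_subject = 1L,
                       baseline_age_distribution = list(dist = "normal",
                                                        mean = 50, sd = 10),
                       visit_gap_distribution = list(dist = "uniform",
                                                     min = 0.5, max = 2.5),
                       beta_between = 0,
                       beta_within = 0,
                       age_effect = c(1, 0, 0),
                       sex_effect = 0,
                       sex_prob = 0.5,
                       subject_intercept_sd = 1,
                       residual_sd = 1,
                       covariate_between_sd = 1,
                       covariate_within_sd = 0.5,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              visits_per_subject = as.integer(visits_per_subject),
              baseline_age_distribution = baseline_age_distribution,
              visit_gap_distribution = visit_gap_distribution,
              beta_between = beta_between, beta_within = beta_within,
              age_effect = age_effect, sex_effect = sex_effect,
              sex_prob = sex_prob,
              subject_intercept_sd = subject_intercept_sd,
              residual_sd = residual_sd,
              covariate_between_sd = covariate_between_sd,
              covariate_within_sd = covariate_within_sd,
              missing_rate = missing_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop("n_subjects must be a positive integer")
  if (cfg$visits_per_subject < 1L) stop("visits_per_subject must be >= 1")
  if (!is.numeric(cfg$residual_sd) || cfg$residual_sd <= 0)
    stop("invalid config: residual_sd must be > 0")
  for (f in c("subject_intercept_sd", "covariate_between_sd",
              "covariate_within_sd"))
    if (cfg[[f]] < 0) stop("invalid config: ", f, " must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid config: missing_rate must be in [0, 1)")
  if (length(cfg$age_effect) != 3L)
    stop("age_effect must have 3 coefficients (linear, quadratic, cubic)")
  invisible(cfg)
}

## draw n values from a named distribution spec
draw_dist <- function(spec, n) {
  switch(spec$dist,
    normal = stats::rnorm(n, spec$mean, spec$sd),
    uniform = stats::runif(n, spec$min, spec$max),
    gamma = (spec$shift %||% 0) + stats::rgamma(n, shape = spec$shape,
                                                rate = spec$rate),
    exponential = (spec$min %||% 0) + stats::rexp(n, spec$rate),
    stop("unknown distribution: ", spec$dist))
}

## mean and sd implied by a distribution spec (used to standardize age)
dist_moments <- function(spec) {
  switch(spec$dist,
    normal = c(spec$mean, spec$sd),
    uniform = c((spec$min + spec$max) / 2, (spec$max - spec$min) / sqrt(12)),
    gamma = c((spec$shift %||% 0) + spec$shape / spec$rate,
              sqrt(spec$shape) / spec$rate),
    exponential = c((spec$min %||% 0) + 1 / spec$rate, 1 / spec$rate),
    stop("unknown distribution: ", spec$dist))
}

#' Simulate a longitudinal (or cross-sectional) cohort
#'
#' Generates a cohort table from the model described in [sim_config()]. With
#' `visits_per_subject = 1` the result is a valid cross-sectional table.
#' Deterministic given the config's seed; visit ages strictly increase within
#' subject (visit gaps are floored at 0.1 years).
#'
#' @param config a [sim_config()].
#' @return a [as_cohort_table()] with covariate column `x` and outcome `y`.
#' @export
simulate_longitudinal_study <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_subjects
    v <- config$visits_per_subject
    age0 <- draw_dist(config$baseline_age_distribution, n)
    sex <- stats::rbinom(n, 1L, config$sex_prob)
    u <- stats::rnorm(n, 0, config$subject_intercept_sd)
    b <- stats::rnorm(n, 0, config$covariate_between_sd)

    subject_id <- rep(seq_len(n), each = v)
    visit_index <- rep(seq_len(v) - 1L, times = n)
    gaps <- pmax(0.1, draw_dist(config$visit_gap_distribution, n * v))
    gaps[visit_index == 0L] <- 0
    age <- age0[subject_id] +
      stats::ave(gaps, subject_id, FUN = cumsum)

    w <- stats::rnorm(n * v, 0, config$covariate_within_sd)
    w[visit_index == 0L] <- 0  # baseline anchors the subject level
    x <- b[subject_id] + w

    mo <- dist_moments(config$baseline_age_distribution)
    z <- (age - mo[1]) / mo[2]
    f_age <- config$age_effect[1] * z + config$age_effect[2] * z^2 +
      config$age_effect[3] * z^3
    y <- f_age + config$sex_effect * sex[subject_id] +
      config$beta_between * b[subject_id] + config$beta_within * w +
      u[subject_id] + stats::rnorm(n * v, 0, config$residual_sd)

    tab <- data.frame(subject_id = subject_id, visit_index = visit_index,
                      age = age, sex = sex[subject_id], x = x, y = y)
    if (config$missing_rate > 0) {
      drop <- visit_index > 0L &
        stats::runif(n * v) < config$missing_rate
      tab <- tab[!drop, , drop = FALSE]
    }
    as_cohort_table(tab)
  })
}

#' Simulate a multi-study collection
#'
#' Generates a list of cohorts whose design features (mean age, SD of age,
#' skewness, cross-sectional vs longitudinal) vary as specified, emulating
#' the heterogeneous study collections that feed effect-size meta-regression.
#' Per-study seeds are derived reproducibly from the master seed with
#' [derive_seeds()], so individual studies can be regenerated independently.
#'
#' @param study_specs list of [sim_config()] objects (length >= 2); each
#'   config's own seed is ignored in favour of the derived one.
#' @param seed master seed.
#' @return named list of cohort tables (`study_1`, `study_2`, ...), each with
#'   a `study_id` column.
#' @export
simulate_multistudy_collection <- function(study_specs, seed = 1L) {
  if (length(study_specs) < 2L)
    stop("need at least 2 study specs")
  seeds <- derive_seeds(seed, length(study_specs))
  out <- vector("list", length(study_specs))
  for (k in seq_along(study_specs)) {
    cfg <- study_specs[[k]]
    cfg$seed <- seeds[k]
    tab <- simulate_longitudinal_study(cfg)
    tab$study_id <- paste0("study_", k)
    out[[k]] <- tab
  }
  names(out) <- paste0("study_", seq_along(out))
  out
}

#' Simulate a two-wave cohort with a noisy behavioural covariate
#'
#' Two visits per subject; the observed covariate carries extra visit-level
#' measurement noise on top of its latent value, emulating behavioural scores
#' that fluctuate with time of day, sleep and instrument noise while the
#' outcome (a structural brain measure) stays precise. The outcome is driven
#' by the latent covariate components, so with `beta_within = 0` the
#' within-subject change of the outcome is independent of the observed
#' covariate change.
#'
#' @param config a [sim_config()] with `visits_per_subject = 2`.
#' @param covariate_measurement_noise_sd SD of the visit-level measurement
#'   noise added to the observed covariate (>= 0).
#' @return a cohort table with columns `x` (observed covariate), `x_latent`
#'   and `y`.
#' @export
simulate_two_wave_behavioral <- function(config,
                                         covariate_measurement_noise_sd = 0) {
  if (config$visits_per_subject != 2L)
    stop("simulate_two_wave_behavioral requires visits_per_subject = 2")
  if (covariate_measurement_noise_sd < 0)
    stop("covariate_measurement_noise_sd must be >= 0")
  tab <- simulate_longitudinal_study(config)
  with_seed(config$seed + 1L, {
    tab$x_latent <- tab$x
    tab$x <- tab$x_latent +
      stats::rnorm(nrow(tab), 0, covariate_measurement_noise_sd)
  })
  tab
}

#' Site-effect configuration
#'
#' @param n_sites number of sites (>= 1).
#' @param additive_shift_sd SD of the site-specific additive outcome shift.
#' @param scale_sd SD, on the log scale, of the site-specific multiplicative
#'   factor applied to the outcome.
#' @param assignment subject-to-site allocation rule; `"uniform"` assigns each
#'   subject to a site uniformly at random (constant across its visits).
#' @return a `site_config` list.
#' @export
site_config <- function(n_sites, additive_shift_sd = 0, scale_sd = 0,
                        assignment = "uniform") {
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (additive_shift_sd < 0 || scale_sd < 0)
    stop("site effect SDs must be >= 0")
  structure(list(n_sites = as.integer(n_sites),
                 additive_shift_sd = additive_shift_sd,
                 scale_sd = scale_sd,
                 assignment = match.arg(assignment, "uniform")),
            class = "site_config")
}

#' Inject additive and multiplicative site effects
#'
#' Assigns every subject to exactly one site (constant across visits), then
#' shifts each outcome column by a site-specific additive constant
#' (N(0, `additive_shift_sd`)) and scales it by a site-specific factor
#' (log-normal with log-SD `scale_sd`). This creates the between-site
#' heterogeneity that harmonization procedures are designed to remove.
#'
#' @param table a non-empty cohort table.
#' @param site_cfg a [site_config()].
#' @param seed integer seed.
#' @param outcomes outcome column names to perturb (default `"y"`).
#' @return the table with a `site_id` column and perturbed outcomes.
#' @export
inject_site_effects <- function(table, site_cfg, seed = 1L, outcomes = "y") {
  if (nrow(table) == 0L) stop("table is empty")
  subj <- unique(table$subject_id)
  with_seed(seed, {
    site_of <- sample.int(site_cfg$n_sites, length(subj), replace = TRUE)
    names(site_of) <- as.character(subj)
    shift <- stats::rnorm(site_cfg$n_sites, 0, site_cfg$additive_shift_sd)
    scale <- exp(stats::rnorm(site_cfg$n_sites, 0, site_cfg$scale_sd))
    s <- site_of[as.character(table$subject_id)]
    table$site_id <- paste0("site_", s)
    for (oc in outcomes)
      table[[oc]] <- table[[oc]] * scale[s] + shift[s]
  })
  table
}
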