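#' Target sampling distribution shapes
#'
#' Defines the target covariate distributions used to reweight bootstrap
#' resamples. With `u = (x - c)/h` mapping the winsorized support to
#' `[-1, 1]`:
#' * `bell`: density proportional to `(1 - u^2) + floor` — mass in the middle,
#'   smallest covariate variance;
#' * `uniform`: flat;
#' * `u_shaped`: proportional to `u^2 + floor` — mass at the extremes, largest
#'   covariate variance;
#' and with `t = (x - low)/(high - low)` on `[0, 1]`:
#' * `increasing`: proportional to `exp(rate * t)` — favours large
#'   within-subject changes;
#' * `decreasing`: proportional to `exp(-rate * t)`;
#' * `binary_proportion`: targets a class-1 proportion `target_prop` for 0/1
#'   covariates (see [binary_weights()]).
#'
#' The quadratic shapes carry an additive `floor` so the density never
#' vanishes at the centre (U) or edges (bell) and every record keeps a
#' positive selection probability.
#'
#' @param family one of `"bell"`, `"uniform"`, `"u_shaped"`, `"decreasing"`,
#'   `"increasing"`, `"binary_proportion"`.
#' @param support numeric `c(low, high)`: the winsorized support the shape is
#'   defined on. May be `NULL` at construction and supplied when weights are
#'   built.
#' @param floor additive floor for the quadratic shapes (default 0.05).
#' @param rate exponential rate for increasing/decreasing shapes (default 2).
#' @param target_prop target class-1 proportion for binary targets.
#' @return a `target_shape` object.
#' @export
target_shape <- function(family = c("bell", "uniform", "u_shaped",
                                    "decreasing", "increasing",
                                    "binary_proportion"),
                         support = NULL, floor = 0.05, rate = 2,
                         target_prop = NULL) {
  family <- match.arg(family)
  if (!is.null(support)) {
    stopifnot(length(support) == 2L)
    if (support[1] >= support[2]) stop("shape support bounds inverted")
  }
  if (family == "binary_proportion" &&
      (is.null(target_prop) || target_prop <= 0 || target_prop >= 1))
    stop("binary_proportion requires target_prop in (0, 1)")
  if (floor < 0) stop("floor must be >= 0")
  structure(list(family = family, support = support, floor = floor,
                 rate = rate, target_prop = target_prop),
            class = "target_shape")
}

## evaluate the (unnormalized) target density at winsorized values
shape_density <- function(shape, x) {
  s <- shape$support
  if (is.null(s)) stop("target_shape has no support set")
  x <- pmin(pmax(x, s[1]), s[2])
  switch(shape$family,
    uniform = rep(1, length(x)),
    bell = {
      u <- (x - mean(s)) / (diff(s) / 2)
      (1 - u^2) + shape$floor
    },
    u_shaped = {
      u <- (x - mean(s)) / (diff(s) / 2)
      u^2 + shape$floor
    },
    increasing = exp(shape$rate * (x - s[1]) / diff(s)),
    decreasing = exp(-shape$rate * (x - s[1]) / diff(s)),
    stop("shape_density is not defined for family ", shape$family))
}

## fill a shape's support from data if unset
resolve_support <- function(shape, x, winsor_bounds = NULL) {
  if (!is.null(winsor_bounds)) {
    if (winsor_bounds[1] >= winsor_bounds[2])
      stop("winsor bounds inverted")
    shape$support <- winsor_bounds
  } else if (is.null(shape$support)) {
    shape$support <- unname(stats::quantile(x, c(0.05, 0.95)))
  }
  shape
}

#' Local (windowed) frequency of multivariate points
#'
#' For each point, counts the points (itself included) whose coordinates all
#' fall within `± halfwidth` of its own — the k-dimensional closed-window
#' frequency used to flatten an empirical distribution by inverse weighting.
#'
#' @param points numeric vector (1-D) or matrix with k in 1..3 columns.
#' @param halfwidth window half-width (> 0), same units as the coordinates.
#' @return integer vector of counts, one per point.
#' @export
local_frequency <- function(points, halfwidth = 0.5) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1L)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) stop("empty input")
  if (halfwidth <= 0) stop("halfwidth must be > 0")
  if (ncol(points) > 3L) stop("local_frequency supports 1 to 3 dimensions")
  counts <- integer(n)
  chunk <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = chunk)) {
    i <- start:min(start + chunk - 1L, n)
    within <- matrix(TRUE, length(i), n)
    for (d in seq_len(ncol(points))) {
      diff_d <- abs(outer(points[i, d], points[, d], "-"))
      within <- within & (diff_d <= halfwidth)
    }
    counts[i] <- as.integer(rowSums(within))
  }
  counts
}

new_weight_table <- function(df, unit, provenance) {
  if (any(!is.finite(df$weight)) || any(df$weight < 0) ||
      all(df$weight == 0))
    stop("weights must be finite, non-negative and not all zero")
  structure(df, unit = unit, provenance = provenance,
            class = c("weight_table", "data.frame"))
}

#' Cross-sectional targeted sampling weights
#'
#' Builds per-record weights that reshape a covariate's sampling distribution
#' towards a target shape: each record is first inversely weighted by its
#' local frequency (flattening the empirical distribution towards uniform)
#' and then rescaled by the target density. Values outside `winsor_bounds`
#' are clamped to the bounds *for weight assignment only* — the table's
#' stored values are never altered and the analysis always uses the actual
#' values.
#'
#' @param ages numeric covariate vector (one value per record).
#' @param shape a [target_shape()] with family bell, uniform or u_shaped.
#' @param winsor_bounds optional `c(low, high)` winsorization bounds;
#'   defaults to the shape's support, or the 5%/95% sample quantiles when
#'   neither is set.
#' @param halfwidth local-frequency window half-width (default 0.5).
#' @return a `weight_table` with columns `id` (record index) and `weight`.
#' @export
cross_sectional_weights <- function(ages, shape, winsor_bounds = NULL,
                                    halfwidth = 0.5) {
  if (!shape$family %in% c("bell", "uniform", "u_shaped"))
    stop("cross-sectional targets must be bell, uniform or u_shaped")
  shape <- resolve_support(shape, ages, winsor_bounds)
  aw <- pmin(pmax(ages, shape$support[1]), shape$support[2])
  freq <- local_frequency(aw, halfwidth)
  w <- shape_density(shape, aw) / freq
  new_weight_table(data.frame(id = seq_along(ages), weight = w),
                   unit = "record",
                   provenance = list(between = shape, halfwidth = halfwidth,
                                     winsor = shape$support))
}

#' Longitudinal (baseline, follow-up) combination weights
#'
#' Enumerates, per subject, every combination of the baseline record with
#' `n_followups` follow-up records, and weights each combination by
#' independent between- and within-subject targets:
#' `weight = between_density(baseline age) x prod(within_density(age change))
#' / multivariate local frequency`. The inverse multivariate frequency first
#' flattens the joint (baseline age, age change) distribution; the target
#' densities then reshape baseline age and age change independently.
#' Winsorization (baseline to `winsor_between`, changes to `winsor_within`)
#' applies to weighting only.
#'
#' @param table a longitudinal cohort table.
#' @param between_shape [target_shape()] for the baseline covariate (bell /
#'   uniform / u_shaped).
#' @param within_shape [target_shape()] for the change from baseline
#'   (decreasing / uniform / increasing, or bell / u_shaped for behavioural
#'   covariates).
#' @param covariate column the shapes act on (default `"age"`).
#' @param winsor_between,winsor_within optional winsorization bounds; default
#'   to 5%/95% sample quantiles of the respective quantity.
#' @param halfwidth window half-width (default 0.5).
#' @param n_followups follow-ups per sampled subject (1 = pairs, 2 = triples).
#' @return a `weight_table` with columns `subject_id`, `row_baseline`,
#'   `row_f1` (, `row_f2`) and `weight`; unit `"subject_pair"` or
#'   `"subject_triple"`.
#' @export
longitudinal_combination_weights <- function(table, between_shape,
                                             within_shape,
                                             covariate = "age",
                                             winsor_between = NULL,
                                             winsor_within = NULL,
                                             halfwidth = 0.5,
                                             n_followups = 1L) {
  stopifnot(n_followups %in% 1:2)
  x <- table[[covariate]]
  base_idx <- which(table$visit_index == 0L)
  names(base_idx) <- as.character(table$subject_id[base_idx])

  combos <- list()
  for (s in names(base_idx)) {
    f <- which(table$subject_id == table$subject_id[base_idx[[s]]] &
                 table$visit_index > 0L)
    if (length(f) < n_followups) next
    # index combn through seq_along: combn(f, m) enumerates 1:f for scalar f
    sets <- matrix(f[utils::combn(seq_along(f), n_followups)],
                   nrow = n_followups)
    combos[[s]] <- cbind(base = base_idx[[s]], t(sets))
  }
  if (!length(combos))
    stop("no subject has a baseline plus ", n_followups, " follow-up(s)")
  cm <- do.call(rbind, combos)

  x_base <- x[cm[, 1]]
  x_change <- matrix(x[cm[, -1, drop = FALSE]] - x_base, ncol = n_followups)

  between_shape <- resolve_support(between_shape, x_base, winsor_between)
  within_shape <- resolve_support(within_shape, as.vector(x_change),
                                  winsor_within)
  wb <- pmin(pmax(x_base, between_shape$support[1]), between_shape$support[2])
  wc <- pmin(pmax(x_change, within_shape$support[1]), within_shape$support[2])

  freq <- local_frequency(cbind(wb, wc), halfwidth)
  dens_within <- apply(matrix(shape_density(within_shape, wc),
                              ncol = n_followups), 1, prod)
  w <- shape_density(between_shape, wb) * dens_within / freq

  df <- data.frame(subject_id = table$subject_id[cm[, 1]],
                   row_baseline = cm[, 1])
  for (j in seq_len(n_followups)) df[[paste0("row_f", j)]] <- cm[, j + 1L]
  df$weight <- w
  new_weight_table(df,
                   unit = if (n_followups == 1L) "subject_pair"
                          else "subject_triple",
                   provenance = list(between = between_shape,
                                     within = within_shape,
                                     halfwidth = halfwidth,
                                     winsor_between = between_shape$support,
                                     winsor_within = within_shape$support))
}

#' Weights targeting a class proportion for a binary covariate
#'
#' For a 0/1 covariate, weights class 1 proportionally to
#' `target_prop / prevalence` and class 0 to
#' `(1 - target_prop) / (1 - prevalence)`, so resamples have expected class-1
#' proportion `target_prop`. A 50% target maximizes, and an extreme target
#' (e.g. 10%) shrinks, the covariate's between-subject variance.
#'
#' @param values 0/1 vector (both classes must be present).
#' @param target_prop target class-1 proportion in (0, 1).
#' @return a `weight_table` with columns `id` and `weight`.
#' @export
binary_weights <- function(values, target_prop) {
  if (target_prop <= 0 || target_prop >= 1)
    stop("target_prop must be in (0, 1)")
  if (!all(values %in% c(0, 1))) stop("values must be 0/1")
  prev <- mean(values)
  if (prev == 0 || prev == 1) stop("both classes must be present")
  w <- ifelse(values == 1, target_prop / prev, (1 - target_prop) / (1 - prev))
  new_weight_table(data.frame(id = seq_along(values), weight = w),
                   unit = "record",
                   provenance = list(
                     between = target_shape("binary_proportion",
                                            target_prop = target_prop)))
}

#' Weighted bootstrap resampling of a cohort table
#'
#' Draws `n` units with replacement with probability proportional to their
#' weights and materializes a new cohort table. Record units yield one row
#' each (a cross-sectional resample); `subject_pair` / `subject_triple` units
#' yield a baseline row plus the selected follow-up(s), re-indexed as visits
#' 0, 1(, 2). Every sampled unit becomes a fresh subject so resampled copies
#' are independent clusters. Deterministic given `seed`.
#'
#' @param table the source cohort table.
#' @param weights a `weight_table` whose units refer to `table` rows.
#' @param n number of units to draw (>= 1).
#' @param seed integer seed.
#' @return a cohort table of the resample.
#' @export
weighted_bootstrap <- function(table, weights, n, seed = 1L) {
  stopifnot(n >= 1L)
  if (all(weights$weight == 0)) stop("all weights are zero")
  unit <- attr(weights, "unit", exact = TRUE)
  pick <- with_seed(seed,
                    sample.int(nrow(weights), n, replace = TRUE,
                               prob = weights$weight))
  if (unit == "record") {
    out <- table[weights$id[pick], , drop = FALSE]
    out$subject_id <- seq_len(n)
    out$visit_index <- 0L
    design <- "cross-sectional"
  } else {
    fcols <- grep("^row_f", names(weights), value = TRUE)
    rows <- cbind(weights$row_baseline[pick],
                  vapply(fcols, function(cn) weights[[cn]][pick],
                         numeric(n)))
    k <- ncol(rows)
    out <- table[as.vector(t(rows)), , drop = FALSE]
    out$subject_id <- rep(seq_len(n), each = k)
    out$visit_index <- rep(0:(k - 1L), times = n)
    design <- "longitudinal"
  }
  rownames(out) <- NULL
  structure(out, design = design, class = c("cohort_table", "data.frame"))
}

#' Run a targeted-sampling design experiment
#'
#' The bootstrap engine behind the design comparisons: for every sampling
#' scheme and every sample size in `n_grid`, draws `B` weighted bootstrap
#' resamples, fits the association model on each, and records the RESI and
#' the Wald p-value of the tested terms. Summaries per (scheme, n) are the
#' mean RESI across replicates, its 2.5%/97.5% percentile band, and the
#' replicate p-values for downstream power/replicability estimation.
#'
#' @param table the source cohort table.
#' @param schemes named list of `weight_table`s (one per scheme).
#' @param n_grid integer vector of resample sizes (units per resample).
#' @param B replicates per (scheme, n) cell (default 1000).
#' @param formula association model formula.
#' @param terms term labels whose effect is tracked.
#' @param seed master seed; replicate seeds are derived from it.
#' @return a `scheme_experiment`: `summary` data.frame (scheme, n, mean_S,
#'   ci_low, ci_high, n_failed) and `replicates` data.frame (scheme, n, rep,
#'   S, p).
#' @export
run_scheme_experiment <- function(table, schemes, n_grid, B = 1000L,
                                  formula, terms, seed = 1L) {
  stopifnot(length(schemes) >= 1L, B >= 1L, all(n_grid >= 1L))
  if (is.null(names(schemes)) || any(names(schemes) == ""))
    stop("schemes must be a named list of weight tables")
  cells <- expand.grid(scheme = names(schemes), n = n_grid,
                       stringsAsFactors = FALSE)
  seeds <- matrix(derive_seeds(seed, nrow(cells) * B), nrow = nrow(cells))
  reps <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    wt <- schemes[[cells$scheme[ci]]]
    design <- if (attr(wt, "unit") == "record") "cross-sectional"
              else "longitudinal"
    S <- p <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      bt <- weighted_bootstrap(table, wt, cells$n[ci], seed = seeds[ci, b])
      res <- tryCatch({
        fit <- fit_study_model(bt, formula, design = design)
        wtst <- wald_test(fit, terms)
        c(resi_point(wtst$T2, wtst$m, fit$n_subjects), wtst$p)
      }, error = function(e) c(NA_real_, NA_real_))
      S[b] <- res[1]; p[b] <- res[2]
    }
    reps[[ci]] <- data.frame(scheme = cells$scheme[ci], n = cells$n[ci],
                             rep = seq_len(B), S = S, p = p)
  }
  replicates <- do.call(rbind, reps)
  summary <- do.call(rbind, lapply(reps, function(r) {
    ok <- !is.na(r$S)
    qs <- if (sum(ok) >= 2)
      stats::quantile(r$S[ok], c(0.025, 0.975), type = 1, names = FALSE)
    else c(NA_real_, NA_real_)
    data.frame(scheme = r$scheme[1], n = r$n[1], mean_S = mean(r$S[ok]),
               ci_low = qs[1], ci_high = qs[2], n_failed = sum(!ok))
  }))
  structure(list(summary = summary, replicates = replicates,
                 n_grid = n_grid, B = B, terms = terms),
            class = "scheme_experiment")
}

#' @export
print.scheme_experiment <- function(x, ...) {
  cat(sprintf("targeted-sampling experiment: %d scheme(s) x n in {%s}, B = %d\n",
              length(unique(x$summary$scheme)),
              paste(x$n_grid, collapse = ", "), x$B))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
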