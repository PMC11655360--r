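#' Run the end-to-end design-analysis pipeline
#'
#' Orchestrates a full desk-scale run from one configuration: simulate a
#' multi-study collection, inject and remove site effects, fit the
#' study-level association models, estimate effect sizes, run the
#' targeted-sampling bootstrap experiment, convert results into
#' power/replicability summaries, and meta-regress study-level effect sizes
#' on design features. Each stage writes its outputs (CSV/JSON) to the run
#' directory and a `manifest.json` records every file with its MD5 hash, the
#' seed and the package version, so re-running with the same config
#' reproduces the outputs exactly.
#'
#' The configuration is an R list (or a YAML file path) with elements:
#' * `studies`: list of [sim_config()] argument lists for the collection;
#' * `site`: optional [site_config()] argument list (stage skipped if absent);
#' * `model`: list with `formula` (character) and `terms`;
#' * `sampling`: optional list with `study` (index of the source study),
#'   `schemes` (named list of lists with `between`/`within` shape family
#'   names), `n_grid`, `B`; stage skipped if absent;
#' * `power`: list with `alpha` (default 0.05) and `replicability` target
#'   (default 0.8);
#' * `seed`: master seed.
#'
#' @param config configuration list or path to a YAML file.
#' @param out_dir run directory (created if needed).
#' @return the run directory path, invisibly; stage outputs as files.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  seeds <- derive_seeds(seed, 4L)
  alpha <- config$power$alpha %||% 0.05
  repl_target <- config$power$replicability %||% 0.8
  formula <- stats::as.formula(config$model$formula)
  terms <- config$model$terms

  # stage 1: simulate the study collection
  specs <- lapply(config$studies, function(a) do.call(sim_config, a))
  studies <- simulate_multistudy_collection(specs, seed = seeds[1])

  # stage 2: site effects in, then residualized back out
  if (!is.null(config$site)) {
    scfg <- do.call(site_config, config$site)
    site_seeds <- derive_seeds(seeds[2], length(studies))
    for (k in seq_along(studies)) {
      studies[[k]] <- inject_site_effects(studies[[k]], scfg,
                                          seed = site_seeds[k])
      studies[[k]] <- remove_site_effects(studies[[k]])
    }
  }
  for (k in seq_along(studies))
    write_cohort(studies[[k]], file.path(out_dir,
                                         paste0(names(studies)[k], ".csv")))

  # stage 3: study-level fits + effect sizes + design summaries
  est <- lapply(seq_along(studies), function(k) {
    tab <- studies[[k]]
    fit <- fit_study_model(tab, formula)
    es <- resi_for_terms(fit, terms)
    cbind(summarize_design(tab, study_id = names(studies)[k]),
          S_hat = es$S_hat, T2 = es$T2, m = es$m, p = es$p,
          df_model = fit$df_model,
          # large-sample bootstrap-free SE surrogate: delta-method scale
          se = pmax(1 / sqrt(2 * fit$n_subjects), 1e-6))
  })
  study_table <- do.call(rbind, est)
  utils::write.csv(study_table, file.path(out_dir, "study_estimates.csv"),
                   row.names = FALSE)

  # stage 4: targeted-sampling experiment on one designated study
  experiment <- NULL
  if (!is.null(config$sampling)) {
    sp <- config$sampling
    src <- studies[[sp$study %||% 1L]]
    schemes <- lapply(sp$schemes, function(s) {
      if (cohort_design(src) == "longitudinal")
        longitudinal_combination_weights(
          src, target_shape(s$between), target_shape(s$within %||% "uniform"))
      else
        cross_sectional_weights(src$age, target_shape(s$between))
    })
    experiment <- run_scheme_experiment(src, schemes,
                                        n_grid = unlist(sp$n_grid),
                                        B = sp$B %||% 200L,
                                        formula = formula, terms = terms,
                                        seed = seeds[3])
    utils::write.csv(experiment$summary,
                     file.path(out_dir, "scheme_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(experiment$replicates,
                     file.path(out_dir, "scheme_replicates.csv"),
                     row.names = FALSE)
  }

  # stage 5: power / replicability summaries
  power_rows <- power_summary(study_table, experiment, alpha, repl_target)
  utils::write.csv(power_rows, file.path(out_dir, "power_summary.csv"),
                   row.names = FALSE)

  # stage 6: meta-regression (needs enough studies)
  meta_out <- NULL
  if (nrow(study_table) >= 13L) {
    meta <- fit_meta_regression(study_table, model = "age")
    meta_out <- list(coefficients = as.list(meta$coefficients),
                     robust_se = as.list(meta$robust_se),
                     pvalues = as.list(meta$pvalues))
    jsonlite::write_json(meta_out, file.path(out_dir, "meta_age.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    seed = seed, package_version = as.character(utils::packageVersion(
      "bwasdesign")),
    config = config,
    files = {
      fs <- setdiff(list.files(out_dir), "manifest.json")
      stats::setNames(as.list(unname(tools::md5sum(file.path(out_dir, fs)))),
                      fs)
    })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

validate_run_config <- function(config) {
  if (is.null(config$studies) || !length(config$studies))
    stop("config must define at least one study under 'studies'")
  if (is.null(config$model$formula) || is.null(config$model$terms))
    stop("config must define model$formula and model$terms")
  vars <- all.vars(stats::as.formula(config$model$formula))
  known <- c("subject_id", "visit_index", "age", "sex", "site_id",
             "study_id", "x", "x_latent", "y")
  bad <- setdiff(vars, known)
  if (length(bad))
    stop("model references columns no stage produces: ",
         paste(bad, collapse = ", "))
  invisible(config)
}

## per-study and per-(scheme, n) power / replicability / required-N rows
power_summary <- function(study_table, experiment, alpha, repl_target) {
  rows <- lapply(seq_len(nrow(study_table)), function(k) {
    st <- study_table[k, ]
    pw <- power_ncf(st$S_hat, st$n_subjects, df_model = st$df_model,
                    m = st$m, alpha = alpha)
    data.frame(source = st$study_id, scheme = "full-data", n = st$n_subjects,
               mean_S = st$S_hat, power = pw,
               replicability = replicability_from_power(pw),
               n_for_target = if (st$S_hat > 0)
                 n_for_replicability(st$S_hat, repl_target,
                                     df_model = st$df_model, m = st$m,
                                     alpha = alpha) else NA_integer_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(experiment)) {
    sm <- experiment$summary
    df_model <- study_table$df_model[1]
    m <- study_table$m[1]
    exp_rows <- lapply(seq_len(nrow(sm)), function(k) {
      reps <- experiment$replicates
      pvals <- reps$p[reps$scheme == sm$scheme[k] & reps$n == sm$n[k]]
      ep <- empirical_power(pvals, alpha)
      mS <- sm$mean_S[k]
      data.frame(source = "scheme-experiment", scheme = sm$scheme[k],
                 n = sm$n[k], mean_S = mS, power = ep$estimate,
                 replicability = ep$replicability,
                 n_for_target = if (!is.na(mS) && mS > 0)
                   n_for_replicability(mS, repl_target,
                                       df_model = df_model, m = m,
                                       alpha = alpha) else NA_integer_)
    })
    out <- rbind(out, do.call(rbind, exp_rows))
  }
  out
}

#' Summary report comparing sampling schemes and designs
#'
#' Reads a completed run directory and assembles the decision-support table:
#' per scheme and sample size, the mean RESI, empirical replicability, and
#' the sample size required for the configured replicability target; plus
#' the per-study full-data rows. Schemes are ordered by mean RESI so the
#' most efficient design reads first.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return the comparison data.frame (also printed).
#' @export
compare_designs_report <- function(run_dir) {
  path <- file.path(run_dir, "power_summary.csv")
  if (!file.exists(path))
    stop("missing stage output: ", path, "; run run_pipeline() first")
  out <- utils::read.csv(path)
  out <- out[order(out$source, -out$mean_S), ]
  rownames(out) <- NULL
  out
}
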