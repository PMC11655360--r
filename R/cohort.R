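#' Long-format cohort tables
#'
#' A `cohort_table` is a plain `data.frame` in long format — one row per
#' (subject, visit) — with the columns `subject_id`, `visit_index` (0-based,
#' 0 = baseline), `age` (years), `sex` (0/1), optionally `site_id` and
#' `study_id`, plus any number of covariate and outcome columns. A `"design"`
#' attribute records whether the table is `"cross-sectional"` or
#' `"longitudinal"`.
#'
#' `as_cohort_table()` validates the structure and applies the curation rule
#' used throughout the package: a table in which fewer than 3 subjects have
#' more than one visit is demoted to cross-sectional and reduced to its
#' baseline rows, because so few repeated subjects cannot support a
#' longitudinal working-correlation estimate.
#'
#' @param x a data.frame with at least `subject_id`, `visit_index`, `age`,
#'   `sex` columns.
#' @param design optional design label; inferred from the data when `NULL`.
#' @return a `cohort_table` (data.frame with a `design` attribute).
#' @export
as_cohort_table <- function(x, design = NULL) {
  stopifnot(is.data.frame(x))
  req <- c("subject_id", "visit_index", "age", "sex")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("cohort table is missing required columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(x[c("subject_id", "visit_index")]))
    stop("(subject_id, visit_index) pairs must be unique")
  n_rep <- sum(tabulate(factor(x$subject_id)) > 1L)
  if (n_rep < 3L || identical(design, "cross-sectional")) {
    # curation rule: demote to cross-sectional, keep baseline rows only
    keep <- x$visit_index == stats::ave(x$visit_index, x$subject_id, FUN = min)
    x <- x[keep, , drop = FALSE]
    design <- "cross-sectional"
  } else if (is.null(design)) {
    design <- "longitudinal"
  }
  rownames(x) <- NULL
  structure(x, design = match.arg(design, c("cross-sectional", "longitudinal")),
            class = c("cohort_table", "data.frame"))
}

#' Design type of a cohort table
#'
#' Returns the stored `"design"` attribute when present, otherwise infers it:
#' a table with at least 3 subjects having more than one row is longitudinal.
#'
#' @param table a cohort table or compatible data.frame.
#' @return `"cross-sectional"` or `"longitudinal"`.
#' @export
cohort_design <- function(table) {
  d <- attr(table, "design", exact = TRUE)
  if (!is.null(d)) return(d)
  if (sum(tabulate(factor(table$subject_id)) > 1L) >= 3L)
    "longitudinal" else "cross-sectional"
}

#' Number of distinct subjects
#' @param table a cohort table.
#' @return integer count of unique `subject_id` values.
#' @export
n_subjects <- function(table) length(unique(table$subject_id))

## baseline rows: smallest visit_index per subject
baseline_rows <- function(table) {
  keep <- table$visit_index ==
    stats::ave(table$visit_index, table$subject_id, FUN = min)
  table[keep, , drop = FALSE]
}

#' Write / read a cohort table as CSV with a JSON metadata sidecar
#'
#' The CSV holds the rows in a fixed column order (required columns first);
#' the sidecar `<path>.meta.json` records the design type and column roles so
#' the table round-trips losslessly.
#'
#' @param table a cohort table.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort table.
#' @export
write_cohort <- function(table, path) {
  req <- c("subject_id", "visit_index", "age", "sex")
  opt <- intersect(c("site_id", "study_id"), names(table))
  other <- setdiff(names(table), c(req, opt))
  out <- as.data.frame(table)[c(req, opt, other)]
  utils::write.csv(out, path, row.names = FALSE)
  meta <- list(design = cohort_design(table), columns = names(out))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  design <- NULL
  if (file.exists(meta_path))
    design <- jsonlite::read_json(meta_path)$design
  as_cohort_table(x, design = design)
}
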