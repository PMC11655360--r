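#' Derive reproducible child seeds from a master seed
#'
#' One master seed governs a whole experiment; per-study, per-replicate and
#' per-bootstrap streams use child seeds produced by this rule so that
#' replicates can be re-run (or parallelized) independently without sharing
#' RNG state. The rule is: seed the generator with the master seed and draw
#' `n` integers uniformly from 1..(2^31 - 2).
#'
#' @param seed master seed (single integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483645L, n, replace = FALSE)
}

## run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## adjusted Fisher-Pearson sample skewness (bias-corrected g1, the flavour
## spreadsheet software and e1071 type = 2 report)
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(0)
  g1 <- mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
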