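## Generalized estimating equations for the identity link / Gaussian working
## model with an exchangeable working correlation, the marginal model used for
## longitudinal association analyses here. The exchangeable structure admits a
## closed-form inverse,
##   V_i^{-1} = (1/phi) [ a I - b_k 1 1' ],  a = 1/(1-alpha),
##   b_k = alpha / ((1-alpha) (1 + (k-1) alpha)),
## which lets every cluster sum be computed with rowsum() instead of a loop —
## clusters never have to be touched individually, so fits on thousands of
## subjects take milliseconds. Scale phi and correlation alpha use the
## Liang-Zeger moment estimators; the coefficient covariance is the
## subject-clustered sandwich. Prior observation weights enter as variance
## weights (V_i = phi W^{-1/2} R W^{-1/2}), the frame-count use case.

gee_fit <- function(X, y, id, weights = NULL, tol = 1e-8, maxit = 100L) {
  n <- length(y)
  p <- ncol(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("observation weights must be positive")
  id <- factor(id)
  k_i <- tabulate(id)                      # cluster sizes, by factor level
  sw <- sqrt(weights)
  Xs <- X * sw
  ys <- y * sw

  qrX <- qr(Xs)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("singular design matrix; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, ys)
  alpha <- 0

  cluster_sums <- function(M) rowsum(M, id, reorder = TRUE)

  for (iter in seq_len(maxit)) {
    e <- ys - Xs %*% beta                  # weighted-scale residuals
    phi <- sum(e^2) / (n - p)
    # alpha: average pairwise product of standardized residuals
    se_sum <- cluster_sums(e)              # per-cluster residual sums
    pair_sum <- (se_sum^2 - cluster_sums(e^2)) / 2
    n_pairs <- sum(k_i * (k_i - 1)) / 2
    alpha <- if (n_pairs > p) sum(pair_sum) / ((n_pairs - p) * phi) else 0
    alpha <- max(min(alpha, 0.99), -0.99 / max(k_i - 1, 1))

    a <- 1 / (1 - alpha)
    b_k <- alpha / ((1 - alpha) * (1 + (k_i - 1) * alpha))

    S <- cluster_sums(Xs)                  # cluster column sums of X
    sy <- cluster_sums(matrix(ys, ncol = 1))
    A <- a * crossprod(Xs) - crossprod(S, b_k * S)
    rhs <- a * crossprod(Xs, ys) - crossprod(S, b_k * sy)
    beta_new <- solve(A, rhs)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("GEE failed to converge in ", maxit, " iterations (delta = ",
         format(delta), ")")

  # sandwich: sum_i g_i g_i', g_i = X_i' V_i^{-1} e_i (phi cancels in A^-1 B A^-1)
  e <- ys - Xs %*% beta
  a <- 1 / (1 - alpha)
  b_k <- alpha / ((1 - alpha) * (1 + (k_i - 1) * alpha))
  S <- cluster_sums(Xs)
  A <- a * crossprod(Xs) - crossprod(S, b_k * S)
  G <- a * cluster_sums(Xs * as.vector(e)) - (b_k * as.vector(cluster_sums(e))) * S
  B <- crossprod(G)
  Ainv <- solve(A)
  vcov <- Ainv %*% B %*% Ainv

  list(coefficients = stats::setNames(as.vector(beta), colnames(X)),
       vcov = vcov, alpha = alpha, phi = phi,
       n_clusters = nlevels(id), n_obs = n, iterations = iter)
}
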