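# Independent oracle for the graphical lasso: ADMM with an exact
# eigendecomposition prox for the log-det term. Shares no code path with
# the package's block coordinate descent solver.
admmGlasso <- function(S, rho, penalizeDiagonal = TRUE, beta = 1,
                       maxIter = 50000L, tol = 1e-10) {
  p <- nrow(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  Theta <- Z
  for (it in seq_len(maxIter)) {
    A <- beta * (Z - U) - S
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    th <- (e$values + sqrt(e$values^2 + 4 * beta)) / (2 * beta)
    Theta <- e$vectors %*% (th * t(e$vectors))
    M <- Theta + U
    Znew <- sign(M) * pmax(abs(M) - rho / beta, 0)
    if (!penalizeDiagonal) diag(Znew) <- diag(M)
    primal <- max(abs(Theta - Znew))
    dual <- beta * max(abs(Znew - Z))
    Z <- Znew
    U <- U + Theta - Z
    if (primal < tol && dual < tol) break
  }
  pen <- sum(abs(Z))
  if (!penalizeDiagonal) pen <- pen - sum(abs(diag(Z)))
  obj <- -determinant(Theta, logarithm = TRUE)$modulus[1] +
    sum(S * Theta) + rho * pen
  list(Theta = Theta, Z = Z, objective = obj,
       support = abs(Z) > 0, iterations = it)
}

# random symmetric positive-definite covariance with O(1) entries
randomSpd <- function(p, jitter = 0.5) {
  A <- matrix(stats::rnorm(p * p), p)
  crossprod(A) / p + jitter * diag(p)
}
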