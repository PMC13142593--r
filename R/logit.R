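# Ridge-penalized logistic regression by iteratively reweighted least
# squares. Minimizes -loglik(beta0, beta) + lambda * ||beta||^2 with the
# intercept unpenalized; the (small) fixed penalty guarantees a finite
# deterministic solution under complete separation.
.ridgeLogit <- function(X, y, lambda = 1e-3, maxit = 200, tol = 1e-10) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(2 * lambda, p - 1L)), p)
  beta <- numeric(p)
  obj <- function(b) {
    eta <- drop(Xd %*% b)
    sum(log1p(exp(-(2 * y - 1) * eta))) + lambda * sum(b[-1L]^2)
  }
  objOld <- obj(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * w) + pen
    g <- crossprod(Xd, y - mu) - c(0, 2 * lambda * beta[-1L])
    step <- drop(solve(H, g))
    # halving line search keeps the penalized objective decreasing
    s <- 1
    repeat {
      betaNew <- beta + s * step
      objNew <- obj(betaNew)
      if (objNew <= objOld + 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    conv <- abs(objOld - objNew) < tol * (abs(objOld) + tol)
    beta <- betaNew
    objOld <- objNew
    if (conv) break
  }
  names(beta) <- colnames(Xd)
  beta
}
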