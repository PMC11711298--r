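# Single-variance-component REML via spectral decomposition.
#
# Model: y ~ N(X b, sigma2g * (K + delta * I)) with delta = sigma2e/sigma2g.
# With K = U diag(d) U', rotate once and profile the restricted likelihood
# over log(delta); the 1-D optimum is found by golden-section/Brent search on
# log(delta) in [lower, upper] (natural log), tolerance `tol`.
remlSpectral <- function(y, X, eig, lower = -10, upper = 10, tol = 1e-6) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  d <- eig$values
  if (min(d) < -1e-8 * max(abs(d), 1))
    stop("kinship matrix is not positive semidefinite within tolerance", call. = FALSE)
  d <- pmax(d, 0)
  U <- eig$vectors
  ty <- drop(crossprod(U, y))
  tX <- crossprod(U, X)

  profile <- function(logDelta) {
    v <- d + exp(logDelta)
    A <- crossprod(tX, tX / v)
    rhs <- crossprod(tX, ty / v)
    b <- solve(A, rhs)
    r <- ty - drop(tX %*% b)
    rss <- sum(r^2 / v)
    # -2 * restricted log-likelihood up to a constant
    (n - p) * log(rss) + sum(log(v)) + determinant(A, logarithm = TRUE)$modulus
  }
  opt <- stats::optimize(profile, c(lower, upper), tol = tol)
  logDelta <- opt$minimum
  boundary <- (logDelta - lower) < 1e-3 || (upper - logDelta) < 1e-3
  delta <- exp(logDelta)
  v <- d + delta
  A <- crossprod(tX, tX / v)
  b <- drop(solve(A, crossprod(tX, ty / v)))
  r <- ty - drop(tX %*% b)
  sigmaG2 <- sum(r^2 / v) / (n - p)
  list(delta = delta, sigmaG2 = sigmaG2, sigmaE2 = delta * sigmaG2,
       h2 = 1 / (1 + delta), beta = b, boundary = boundary,
       minimand = opt$objective)
}
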