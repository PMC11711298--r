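#' @useDynLib gwasGP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.gpFamilies <- c("gblup", "ridge", "lasso", "elasticnet", "krr",
                 "svr_linear", "svr_poly")

setValidity("GPModelSpec", function(object) {
  msg <- character(0)
  if (!object@family %in% .gpFamilies)
    msg <- c(msg, paste("unknown model family:", object@family))
  h <- object@hyper
  chk <- function(name, cond) if (!is.null(h[[name]]) && !cond(h[[name]]))
    msg <<- c(msg, paste("invalid hyperparameter", name))
  chk("lambda", function(x) x > 0)
  chk("lambdaG", function(x) x > 0)
  chk("C", function(x) x > 0)
  chk("epsilon", function(x) x >= 0)
  chk("degree", function(x) x >= 1 && x == round(x))
  chk("l1_fraction", function(x) x >= 0 && x <= 1)
  if (length(msg)) msg else TRUE
})

#' Specify a genomic prediction model
#'
#' One uniform specification for the seven benchmark families. Family-specific
#' hyperparameters are passed by name:
#' \describe{
#'   \item{gblup}{`lambdaG` (variance ratio `sigma2e/sigma2u`); omitted =
#'     estimated by REML on the training data.}
#'   \item{ridge, lasso}{`lambda` (penalty weight in the objective
#'     `(1/2)RSS + lambda * penalty`).}
#'   \item{elasticnet}{`lambda` and `l1_fraction` (`0` = ridge penalty,
#'     `1` = lasso penalty).}
#'   \item{krr}{`lambda`, `kernel` ("poly" default, "linear", "rbf"),
#'     `gamma`, `r`, `degree`.}
#'   \item{svr_linear, svr_poly}{`C`, `epsilon`; the polynomial kernel
#'     `(gamma <x, y> + r)^degree` additionally takes `gamma`, `r`, `degree`.}
#' }
#'
#' @param family one of `r paste0('"', .gpFamilies, '"', collapse = ", ")`.
#' @param ... named hyperparameters (see above).
#' @param standardize centre and scale features inside [fitGP()] (default
#'   TRUE; features are always centred so the intercept decouples; gblup
#'   instead centres raw dosages by training allele frequencies).
#' @return a [GPModelSpec].
#' @export
gpModelSpec <- function(family, ..., standardize = TRUE) {
  new("GPModelSpec", family = family, hyper = list(...),
      standardize = standardize)
}

# kernel matrix from a linear Gram block; for rbf, selfL/selfR are the
# row-wise squared norms belonging to the Gram's rows/columns
applyKernel <- function(gram, kernel, gamma, r, degree, selfL = NULL, selfR = NULL) {
  switch(kernel,
    linear = gram,
    poly = (gamma * gram + r)^degree,
    rbf = exp(-gamma * pmax(outer(selfL, selfR, "+") - 2 * gram, 0)),
    stop("unknown kernel: ", kernel, call. = FALSE))
}

# elastic-net solve at a single (lambda, alpha) with a warm-started geometric
# path from near lambda_max; objective (1/2)RSS + lambda*(a*L1 + (1-a)/2*L2)
solveEnet <- function(Xs, y, lambda, alpha, tol = 1e-7, maxSweeps = 10000,
                      pathLength = 8) {
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xs, yc)))
  start <- if (alpha > 0) lmax / max(alpha, 0.05) * 0.99 else lmax
  lams <- if (lambda < start)
    exp(seq(log(start), log(lambda), length.out = pathLength))
  else lambda
  lams[length(lams)] <- lambda
  fit <- cdEnetPath(Xs, y, lams, alpha, tol, maxSweeps)
  k <- length(lams)
  if (!fit$converged[k])
    stop(sprintf("coordinate descent did not converge within %d sweeps", fit$sweeps[k]),
         call. = FALSE)
  list(beta = fit$beta[, k], b0 = fit$b0[k], sweeps = fit$sweeps[k])
}

# VanRaden GRM pieces tolerant of fold-internal monomorphic columns (they
# contribute zero to both numerator and scaling constant)
vanRadenParts <- function(d) {
  p <- colMeans(d) / 2
  cst <- 2 * sum(p * (1 - p))
  stopIfNot(cst > 0, "all markers monomorphic; cannot build a relationship matrix")
  list(p = p, cst = cst, Wc = sweep(d, 2, 2 * p))
}

#' Fit one genomic prediction model
#'
#' Family contracts:
#' \itemize{
#'   \item `gblup`: intercept-only mixed model `y = mu + u + e` with
#'     `u ~ N(0, G sigma2u)`, `G` the VanRaden GRM of the training rows; the
#'     variance ratio `lambdaG = sigma2e/sigma2u` is taken from the model
#'     specification or
#'     estimated by spectral REML (default); the grand mean is the training
#'     mean, which makes GBLUP and ridge on centred dosages numerically
#'     identical (RR-BLUP equivalence).
#'   \item `ridge`: closed-form solution of `(1/2)RSS + (lambda/2)||beta||^2`
#'     via the dual system `(X X' + lambda I) a = y_c`, `beta = X' a`.
#'   \item `lasso`, `elasticnet`: cyclic coordinate descent with
#'     soft-thresholding on `(1/2)RSS + lambda(a ||beta||_1 +
#'     (1-a)/2 ||beta||_2^2)` (`a = 1` for lasso), warm-started along a
#'     geometric path; convergence when the maximum coefficient change in a
#'     sweep drops below `tol` (default 1e-7), error after `maxSweeps`
#'     (default 10,000).
#'   \item `krr`: dual solution `(K + lambda I)^{-1} y_c` with linear,
#'     polynomial `(gamma <x,y> + r)^degree` (default) or RBF kernel.
#'   \item `svr_linear`, `svr_poly`: epsilon-insensitive support vector
#'     regression solved in the dual (\pkg{kernlab}) on a precomputed kernel
#'     matrix of the standardized features.
#' }
#'
#' @param spec a [GPModelSpec].
#' @param W training dosage/feature matrix (accessions x markers,
#'   missing-free; rows match `y`).
#' @param y training corrected phenotypes.
#' @param gram optional precomputed `tcrossprod` of the standardized training
#'   features (performance path for cross-validation; must match `W` after
#'   standardization).
#' @return a [GPModel].
#' @export
fitGP <- function(spec, W, y, gram = NULL) {
  validObject(spec)
  stopIfNot(!anyNA(W), "fitGP requires a missing-free matrix")
  stopIfNot(nrow(W) == length(y), "rows of W must match y")
  h <- spec@hyper
  fam <- spec@family
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  p <- ncol(W)
  state <- list()
  b0 <- 0

  if (fam == "gblup") {
    vr <- vanRadenParts(W)
    G <- tcrossprod(vr$Wc) / vr$cst
    lambdaG <- h$lambdaG
    if (is.null(lambdaG)) {
      eig <- eigen(G, symmetric = TRUE)
      lambdaG <- remlSpectral(y, matrix(1, length(y)), eig)$delta
    }
    b0 <- mean(y)
    alphaVec <- solve(G + lambdaG * diag(nrow(G)), y - b0)
    state <- list(Wc = vr$Wc, p = vr$p, cst = vr$cst,
                  alphaVec = drop(alphaVec), lambdaG = lambdaG)
  } else {
    std <- standardizeTrain(W, scale = spec@standardize)
    Xs <- std$X
    if (fam %in% c("ridge", "krr", "svr_linear", "svr_poly") && is.null(gram))
      gram <- tcrossprod(Xs)
    if (fam == "ridge") {
      lambda <- if (is.null(h$lambda)) 1 else h$lambda
      yc <- y - mean(y)
      a <- solve(gram + lambda * diag(nrow(gram)), yc)
      state <- list(std = std, beta = drop(crossprod(Xs, a)))
      b0 <- mean(y)
    } else if (fam %in% c("lasso", "elasticnet")) {
      lambda <- if (is.null(h$lambda)) 1 else h$lambda
      amix <- if (fam == "lasso") 1 else
        (if (is.null(h$l1_fraction)) 0.5 else h$l1_fraction)
      tol <- if (is.null(h$tol)) 1e-7 else h$tol
      maxSweeps <- if (is.null(h$maxSweeps)) 10000 else h$maxSweeps
      sol <- solveEnet(Xs, y, lambda, amix, tol, maxSweeps)
      state <- list(std = std, beta = sol$beta, sweeps = sol$sweeps)
      b0 <- sol$b0
    } else if (fam == "krr") {
      lambda <- if (is.null(h$lambda)) 1 else h$lambda
      kern <- if (is.null(h$kernel)) "poly" else h$kernel
      gamma <- if (is.null(h$gamma) || is.na(h$gamma)) 1 / p else h$gamma
      r <- if (is.null(h$r)) 1 else h$r
      degree <- if (is.null(h$degree)) 2 else h$degree
      self <- rowSums(Xs^2)
      K <- applyKernel(gram, kern, gamma, r, degree, self, self)
      yc <- y - mean(y)
      dual <- tryCatch(solve(K + lambda * diag(nrow(K)), yc),
                       error = function(e)
                         stop("K + lambda*I is numerically singular; increase lambda",
                              call. = FALSE))
      state <- list(std = std, Xs = Xs, dual = drop(dual), kernel = kern,
                    gamma = gamma, r = r, degree = degree, self = self)
      b0 <- mean(y)
    } else { # svr_linear / svr_poly
      C <- if (is.null(h$C)) 1 else h$C
      epsilon <- if (is.null(h$epsilon)) 0.1 else h$epsilon
      kern <- if (fam == "svr_linear") "linear" else "poly"
      gamma <- if (is.null(h$gamma) || is.na(h$gamma)) 1 / p else h$gamma
      r <- if (is.null(h$r)) 0 else h$r
      degree <- if (is.null(h$degree)) 2 else h$degree
      self <- rowSums(Xs^2)
      K <- applyKernel(gram, kern, gamma, r, degree, self, self)
      # fit on the standardized phenotype so C and epsilon are scale-free;
      # predictions are mapped back to trait units
      yCtr <- mean(y)
      ySc <- stats::sd(y)
      if (!is.finite(ySc) || ySc == 0) ySc <- 1
      m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), (y - yCtr) / ySc,
                         type = "eps-svr", C = C, epsilon = epsilon)
      state <- list(std = std, Xs = Xs, model = m,
                    svIdx = kernlab::SVindex(m), kernel = kern,
                    gamma = gamma, r = r, degree = degree, self = self,
                    yCtr = yCtr, ySc = ySc)
      b0 <- 0 # offset lives inside the kernlab model
    }
  }
  new("GPModel", spec = spec, state = state, trainIds = ids,
      intercept = as.numeric(b0))
}

#' Predict from a fitted genomic prediction model
#'
#' Prediction is a pure function of the stored state: penalized families use
#' `intercept + W_std beta`; kernel families the cross-kernel against the
#' training features; gblup the train-test relationship block
#' `mu + G_new,train (G + lambdaG I)^{-1} (y - mu)` with centring by the
#' training allele frequencies.
#'
#' @param model a [GPModel] from [fitGP()].
#' @param Wnew new dosage/feature matrix with the same columns as training.
#' @return numeric vector of predictions, one per row of `Wnew`.
#' @export
predictGP <- function(model, Wnew) {
  st <- model@state
  fam <- model@spec@family
  refCols <- if (fam == "gblup") colnames(st$Wc) else names(st$std$center)
  if (!is.null(colnames(Wnew)) && !is.null(refCols) &&
      !identical(colnames(Wnew), refCols)) {
    bad <- union(setdiff(colnames(Wnew), refCols), setdiff(refCols, colnames(Wnew)))
    if (!length(bad)) bad <- colnames(Wnew)[colnames(Wnew) != refCols]
    stop("marker columns do not match training; offending markers: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (fam == "gblup") {
    stopIfNot(ncol(Wnew) == ncol(st$Wc), "column count mismatch")
    Wn <- sweep(Wnew, 2, 2 * st$p)
    Gcross <- tcrossprod(Wn, st$Wc) / st$cst
    return(drop(model@intercept + Gcross %*% st$alphaVec))
  }
  stopIfNot(ncol(Wnew) == length(st$std$center), "column count mismatch")
  Xn <- applyStandardize(Wnew, st$std)
  if (fam %in% c("ridge", "lasso", "elasticnet"))
    return(drop(model@intercept + Xn %*% st$beta))
  gramNew <- Xn %*% t(st$Xs)
  selfN <- rowSums(Xn^2)
  K <- applyKernel(gramNew, st$kernel, st$gamma, st$r, st$degree, selfN, st$self)
  if (fam == "krr")
    return(drop(model@intercept + K %*% st$dual))
  st$yCtr + st$ySc *
    drop(predict(st$model, kernlab::as.kernelMatrix(K[, st$svIdx, drop = FALSE])))
}

setMethod("predict", "GPModel", function(object, newdata, ...) {
  predictGP(object, newdata)
})

#' Default hyperparameter grids for tuning
#'
#' Documented defaults: `lambda` 13 log-spaced points in `[1e-4, 1e4]`;
#' `l1_fraction` in `{0.1, 0.3, 0.5, 0.7, 0.9}`; `C` in `{0.1, 1, 10, 100}`;
#' `epsilon` in `{0.01, 0.1, 0.5}`; `gamma` in `{1/n_snps, 1e-3, 1e-2}`
#' (`NA` encodes `1/n_snps`, resolved at fit time); `r` in `{0, 1}`;
#' `degree` in `{2, 3}`. GBLUP takes no grid (its variance ratio is REML
#' estimated), so its grid is empty.
#'
#' @param family model family.
#' @param nSnps optional marker count used to resolve the `1/n_snps` gamma.
#' @return data.frame with one row per grid point (zero rows for gblup).
#' @export
defaultGrid <- function(family, nSnps = NULL) {
  lam <- 10^seq(-4, 4, length.out = 13)
  gam <- c(if (is.null(nSnps)) NA_real_ else 1 / nSnps, 1e-3, 1e-2)
  g <- switch(family,
    gblup = data.frame(),
    ridge = data.frame(lambda = lam),
    lasso = data.frame(lambda = lam),
    elasticnet = expand.grid(lambda = lam,
                             l1_fraction = c(0.1, 0.3, 0.5, 0.7, 0.9)),
    krr = expand.grid(lambda = lam, gamma = gam, r = c(0, 1), degree = c(2, 3)),
    svr_linear = expand.grid(C = c(0.1, 1, 10, 100), epsilon = c(0.01, 0.1, 0.5)),
    svr_poly = expand.grid(C = c(0.1, 1, 10, 100), epsilon = c(0.01, 0.1, 0.5),
                           gamma = gam, r = c(0, 1), degree = c(2, 3)),
    stop("unknown model family: ", family, call. = FALSE))
  as.data.frame(g)
}

#' Reduced tuning grids for desk-scale benchmarking
#'
#' Smaller grids covering the same hyperparameter ranges as [defaultGrid()],
#' intended for desk-scale runs and continuous testing where the full grids
#' would dominate run time. Penalty weights are expressed relative to a
#' per-training-fold scale (`lambdaRel`, resolved inside the tuner): the top
#' eigenvalue of the feature Gram matrix for ridge/KRR, and
#' `lambda_max = max |X' y_c|` for lasso/elastic net. This keeps the grid
#' meaningful across traits and fold sizes.
#'
#' @param family model family.
#' @return data.frame of grid points.
#' @export
deskGrid <- function(family) {
  lamRel <- 10^seq(-3, 0.5, length.out = 6)
  lamRelL1 <- 10^seq(-1.7, -0.15, length.out = 5)
  g <- switch(family,
    gblup = data.frame(),
    ridge = data.frame(lambdaRel = lamRel),
    lasso = data.frame(lambdaRel = lamRelL1),
    elasticnet = expand.grid(lambdaRel = lamRelL1, l1_fraction = c(0.25, 0.75)),
    krr = expand.grid(lambdaRel = lamRel, gamma = NA_real_, r = 1, degree = c(2, 3)),
    svr_linear = expand.grid(C = c(1, 10), epsilon = c(0.01, 0.1)),
    svr_poly = expand.grid(C = c(1, 10), epsilon = c(0.01, 0.1),
                           gamma = NA_real_, r = 1, degree = c(2, 3)),
    stop("unknown model family: ", family, call. = FALSE))
  as.data.frame(g)
}
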