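gpData <- function() {
  cachedPanel("gpData", function() {
    sim <- structuredPanel()
    D <- dosageMatrix(imputeMissing(sim$geno))[, 1:600]
    set.seed(55)
    beta <- numeric(600); beta[sample(600, 25)] <- rnorm(25, 0, 0.4)
    y <- drop(sweep(D, 2, colMeans(D)) %*% beta)
    y <- y + rnorm(nrow(D), 0, stats::sd(y) * 0.7)
    list(W = D[1:110, ], Wte = D[111:150, ], y = y[1:110], yte = y[111:150])
  })
}

enetObjective <- function(W, y, b0, beta, lambda, alpha) {
  std <- gwasGP:::standardizeTrain(W)
  r <- y - b0 - drop(std$X %*% beta)
  0.5 * sum(r^2) + lambda * (alpha * sum(abs(beta)) +
                               (1 - alpha) / 2 * sum(beta^2))
}

test_that("model specifications validate their hyperparameters", {
  expect_error(gpModelSpec("boosting"), "unknown model family")
  expect_error(gpModelSpec("ridge", lambda = -1), "lambda")
  expect_error(gpModelSpec("svr_poly", C = 1, degree = 2.5), "degree")
  expect_error(gpModelSpec("elasticnet", lambda = 1, l1_fraction = 2),
               "l1_fraction")
  expect_s4_class(gpModelSpec("krr", lambda = 1, kernel = "rbf"), "GPModelSpec")
})

test_that("default grids have the documented shape", {
  expect_equal(nrow(defaultGrid("ridge")), 13)
  expect_equal(nrow(defaultGrid("lasso")), 13)
  expect_equal(nrow(defaultGrid("elasticnet")), 65)
  expect_equal(nrow(defaultGrid("krr")), 156)
  expect_equal(nrow(defaultGrid("svr_linear")), 12)
  expect_equal(nrow(defaultGrid("svr_poly")), 144)
  expect_equal(nrow(defaultGrid("gblup")), 0)
  expect_error(defaultGrid("mlp"), "unknown model family")
  expect_true((1 / 500) %in% defaultGrid("svr_poly", nSnps = 500)$gamma)
})

test_that("ridge recovers OLS on tall noise-free problems", {
  set.seed(2)
  W <- matrix(rnorm(200 * 40), 200)
  b <- rnorm(40)
  y <- drop(W %*% b) + 3
  m <- fitGP(gpModelSpec("ridge", lambda = 1e-8, standardize = FALSE), W, y)
  expect_lt(max(abs(m@state$beta - b)), 1e-4)
})

test_that("lasso dies above lambda_max and descends its objective", {
  d <- gpData()
  std <- gwasGP:::standardizeTrain(d$W)
  lmax <- max(abs(crossprod(std$X, d$y - mean(d$y))))
  m0 <- fitGP(gpModelSpec("lasso", lambda = lmax * 1.01), d$W, d$y)
  expect_true(all(m0@state$beta == 0))
  for (spec in list(gpModelSpec("lasso", lambda = lmax / 20),
                    gpModelSpec("elasticnet", lambda = lmax / 20,
                                l1_fraction = 0.4),
                    gpModelSpec("ridge", lambda = 5))) {
    m <- fitGP(spec, d$W, d$y)
    a <- if (spec@family == "lasso") 1
         else if (spec@family == "ridge") 0 else 0.4
    lam <- spec@hyper$lambda
    expect_lt(enetObjective(d$W, d$y, m@intercept, m@state$beta, lam, a),
              enetObjective(d$W, d$y, mean(d$y), numeric(ncol(d$W)), lam, a))
  }
})

test_that("coordinate descent agrees with glmnet on its exact objective", {
  skip_if_not_installed("glmnet")
  d <- gpData()
  n <- nrow(d$W)
  std <- gwasGP:::standardizeTrain(d$W)
  for (a in c(1, 0.4)) {
    lam <- if (a == 1) 30 else 50
    m <- fitGP(gpModelSpec("elasticnet", lambda = lam, l1_fraction = a,
                           tol = 1e-12), d$W, d$y)
    sy <- sqrt(mean((d$y - mean(d$y))^2))
    t1 <- lam * a / n
    t2 <- lam * (1 - a) * sy / n # glmnet scales the L2 term by sd(y)
    lg <- t1 + t2
    f <- glmnet::glmnet(std$X, d$y, alpha = t1 / lg,
                        lambda = lg * c(8, 4, 2, 1), standardize = FALSE,
                        thresh = 1e-16, maxit = 1e7)
    expect_lt(max(abs(as.numeric(f$beta[, 4]) - m@state$beta)), 1e-6)
  }
})

test_that("GBLUP with fixed variance ratio equals matched-penalty ridge", {
  d <- gpData()
  p <- colMeans(d$W) / 2
  cst <- 2 * sum(p * (1 - p))
  lamG <- 1.7
  mG <- fitGP(gpModelSpec("gblup", lambdaG = lamG), d$W, d$y)
  mR <- fitGP(gpModelSpec("ridge", lambda = lamG * cst, standardize = FALSE),
              d$W, d$y)
  expect_lt(max(abs(predictGP(mG, d$Wte) - predictGP(mR, d$Wte))), 1e-8)
})

test_that("kernel and mixture identities hold across families", {
  d <- gpData()
  mR <- fitGP(gpModelSpec("ridge", lambda = 40), d$W, d$y)
  mK <- fitGP(gpModelSpec("krr", kernel = "linear", lambda = 40), d$W, d$y)
  expect_lt(max(abs(predictGP(mK, d$Wte) - predictGP(mR, d$Wte))), 1e-8)
  mE0 <- fitGP(gpModelSpec("elasticnet", lambda = 40, l1_fraction = 0,
                           tol = 1e-11, maxSweeps = 2e5), d$W, d$y)
  expect_lt(max(abs(predictGP(mE0, d$Wte) - predictGP(mR, d$Wte))), 1e-8)
  mL <- fitGP(gpModelSpec("lasso", lambda = 25, tol = 1e-12), d$W, d$y)
  mE1 <- fitGP(gpModelSpec("elasticnet", lambda = 25, l1_fraction = 1,
                           tol = 1e-12), d$W, d$y)
  expect_lt(max(abs(predictGP(mE1, d$Wte) - predictGP(mL, d$Wte))), 1e-8)
})

test_that("prediction contracts: shrinkage limit, duplication, column checks", {
  d <- gpData()
  mInf <- fitGP(gpModelSpec("ridge", lambda = 1e13), d$W, d$y)
  expect_lt(max(abs(predictGP(mInf, d$W) - mean(d$y))), 1e-6)
  mG <- fitGP(gpModelSpec("gblup", lambdaG = 1e10), d$W, d$y)
  expect_lt(max(abs(predictGP(mG, d$W) - mean(d$y))), 1e-4)
  m <- fitGP(gpModelSpec("krr", lambda = 5), d$W, d$y)
  Wdup <- d$Wte[c(1, 1, 2), ]
  pd <- predictGP(m, Wdup)
  expect_equal(pd[1], pd[2])
  bad <- d$Wte[, c(2:ncol(d$Wte), 1)]
  expect_error(predictGP(m, bad), "offending markers")
})

test_that("GBLUP interpolates a genetically identical test accession", {
  d <- gpData()
  m <- fitGP(gpModelSpec("gblup", lambdaG = 1e-6), d$W, d$y)
  clone <- d$W[c(12, 30), , drop = FALSE]
  pr <- predictGP(m, clone)
  expect_lt(max(abs(pr - d$y[c(12, 30)])), 1e-3)
})

test_that("standardized fits are invariant to feature pre-scaling", {
  d <- gpData()
  Wscaled <- d$W
  Wscaled[, 3] <- Wscaled[, 3] * 10
  WteS <- d$Wte
  WteS[, 3] <- WteS[, 3] * 10
  for (fam in list(gpModelSpec("ridge", lambda = 20),
                   gpModelSpec("lasso", lambda = 20, tol = 1e-10))) {
    p1 <- predictGP(fitGP(fam, d$W, d$y), d$Wte)
    p2 <- predictGP(fitGP(fam, Wscaled, d$y), WteS)
    expect_lt(max(abs(p1 - p2)), 1e-6)
  }
})

test_that("SVR with tiny epsilon and large C approaches the exact fit", {
  set.seed(6)
  W <- matrix(rnorm(120 * 8), 120)
  b <- rnorm(8)
  y <- drop(W %*% b) + 1
  m <- fitGP(gpModelSpec("svr_linear", C = 1e4, epsilon = 0,
                         standardize = FALSE), W, y)
  # recover the primal weights from the dual representation (the model is
  # fitted on the standardized phenotype, so weights scale back by sd(y))
  sv <- m@state$svIdx
  alpha <- kernlab::alpha(m@state$model)
  w <- drop(crossprod(m@state$Xs[sv, , drop = FALSE], alpha)) * m@state$ySc
  expect_lt(max(abs(w - b)), 1e-2)
  mp <- fitGP(gpModelSpec("svr_poly", C = 10, epsilon = 0.1, r = 1), W, y)
  expect_gt(stats::cor(predictGP(mp, W), y), 0.9)
})

test_that("fitted models survive a save/load round trip", {
  d <- gpData()
  m <- fitGP(gpModelSpec("krr", lambda = 10), d$W, d$y)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, path)
  m2 <- readRDS(path)
  expect_equal(predictGP(m2, d$Wte), predictGP(m, d$Wte))
})

test_that("non-convergent coordinate descent fails loudly", {
  d <- gpData()
  expect_error(fitGP(gpModelSpec("lasso", lambda = 0.01, tol = 1e-14,
                                 maxSweeps = 5), d$W, d$y),
               "did not converge")
})
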