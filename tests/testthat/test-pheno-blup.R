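blupPanel <- function() {
  cachedPanel("blupPanel", function() {
    cfg <- simGenotypeConfig(200, 2000, nChromosomes = 4, nSubpops = 1,
                             ldRho = 0.4, inbreeding = 0.9, seed = 41)
    sim <- simulateGenotypes(cfg)
    pcfg <- simPhenotypeConfig("T", 50, 0.6, seed = 42)
    ph <- simulatePhenotypes(sim$geno, sim$labels, pcfg)
    list(sim = sim, ph = ph,
         blup = suppressWarnings(fitMultiEnvBlup(ph$trials)))
  })
}

test_that("genotype BLUPs are equivariant under accession relabelling", {
  p <- blupPanel()
  tr <- p$ph$trials
  # swap two accession labels throughout
  swapped <- tr
  swapped$accession[tr$accession == "acc001"] <- "ZZZ"
  swapped$accession[tr$accession == "acc002"] <- "acc001"
  swapped$accession[swapped$accession == "ZZZ"] <- "acc002"
  b1 <- suppressWarnings(fitMultiEnvBlup(tr))
  b2 <- suppressWarnings(fitMultiEnvBlup(swapped))
  y1 <- correctedPhenotypes(b1); y2 <- correctedPhenotypes(b2)
  expect_equal(y1["acc001", 1], y2["acc002", 1], tolerance = 1e-9)
  expect_equal(y1["acc002", 1], y2["acc001", 1], tolerance = 1e-9)
  expect_equal(y1["acc010", 1], y2["acc010", 1], tolerance = 1e-9)
})

test_that("multi-environment BLUP beats single-environment phenotypes", {
  wins <- 0; diffs <- numeric(0)
  for (s in 1:5) {
    cfg <- simGenotypeConfig(150, 1000, nChromosomes = 2, nSubpops = 1,
                             ldRho = 0.3, inbreeding = 0.9, seed = 500 + s)
    sim <- simulateGenotypes(cfg)
    pcfg <- simPhenotypeConfig("T", 40, 0.6, seed = 600 + s)
    ph <- simulatePhenotypes(sim$geno, sim$labels, pcfg)
    g <- ph$truth$perTrait$T$g
    yc <- correctedPhenotypes(suppressWarnings(fitMultiEnvBlup(ph$trials)))[, 1]
    e1 <- ph$trials[ph$trials$environment == "env1", ]
    single <- stats::setNames(e1$value, e1$accession)
    d <- stats::cor(yc, g[names(yc)]) - stats::cor(single[names(yc)], g[names(yc)])
    diffs <- c(diffs, d)
    wins <- wins + (d > 0)
  }
  expect_gte(wins, 4)
  expect_gt(mean(diffs), 0)
})

test_that("confounded or underdetermined designs are rejected", {
  tr <- data.frame(accession = rep(c("a", "b", "c"), each = 2),
                   environment = rep(c("e1", "e2"), 3),
                   group = rep(c("g1", "g2", "g3"), each = 2),
                   trait = "t", value = rnorm(6))
  expect_error(fitMultiEnvBlup(tr), "confounded")
  one <- data.frame(accession = c("a", "b"), environment = "e1", group = "g1",
                    trait = "t", value = c(1, 2))
  expect_error(fitMultiEnvBlup(one), "two environments")
  expect_error(fitMultiEnvBlup(data.frame(x = 1)), "columns")
})

test_that("descriptive statistics match hand arithmetic", {
  tr <- data.frame(accession = c("a", "b", "a", "b"),
                   environment = "e1", group = "g",
                   trait = rep(c("t1", "t2"), each = 2),
                   value = c(2, 4, 5, 5))
  st <- descriptiveStats(tr)
  t1 <- st[st$trait == "t1", ]
  expect_equal(t1$mean, 3); expect_equal(t1$variance, 2)
  expect_equal(t1$cv, sqrt(2) / 3)
  expect_equal(st[st$trait == "t2", "cv"], 0)
  zero <- data.frame(accession = c("a", "b"), environment = "e", group = "g",
                     trait = "z", value = c(-1, 1))
  expect_true(is.na(descriptiveStats(zero)$cv))
  expect_error(descriptiveStats(zero[1, ]), "two observations")
})

test_that("simulated panel CVs fall in the agronomic envelope", {
  p <- blupPanel()
  st <- descriptiveStats(p$ph$trials)
  expect_true(all(st$cv > 0.05 & st$cv < 0.60))
})

test_that("heritability estimation hits its noise-free and null limits", {
  p <- blupPanel()
  g <- p$ph$truth$perTrait$T$g
  geno <- imputeMissing(p$sim$geno)
  hiFit <- suppressWarnings(estimateH2(g, geno))
  expect_gt(hiFit@h2, 0.9)
  expect_equal(hiFit@h2, hiFit@sigma2g / (hiFit@sigma2g + hiFit@sigma2e))
  set.seed(7)
  nulls <- vapply(1:3, function(i) {
    suppressWarnings(estimateH2(namedPheno(geno, rnorm(nAccessions(geno))),
                                geno)@h2)
  }, numeric(1))
  expect_lt(mean(nulls), 0.1)
})

test_that("heritability is invariant to affine rescaling of the phenotype", {
  p <- blupPanel()
  geno <- imputeMissing(p$sim$geno)
  yc <- correctedPhenotypes(p$blup)[, 1]
  h1 <- suppressWarnings(estimateH2(yc, geno)@h2)
  h2 <- suppressWarnings(estimateH2(yc * 3.7 - 11, geno)@h2)
  expect_equal(h1, h2, tolerance = 1e-6)
})

test_that("added residual noise strictly lowers estimated heritability", {
  p <- blupPanel()
  geno <- imputeMissing(p$sim$geno)
  g <- p$ph$truth$perTrait$T$g[accessionIds(geno)]
  means <- vapply(c(0.5, 1.5, 4), function(k) {
    mean(vapply(1:3, function(s) {
      set.seed(1000 * k + s)
      y <- g + rnorm(length(g), 0, k * stats::sd(g))
      suppressWarnings(estimateH2(stats::setNames(y, names(g)), geno)@h2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("REML fixed-effect residuals are orthogonal to the covariates", {
  set.seed(12)
  n <- 80
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  eig <- eigen(K, symmetric = TRUE)
  X <- cbind(1, rnorm(n))
  y <- drop(eig$vectors %*% (sqrt(pmax(eig$values, 0)) * rnorm(n))) + X %*% c(2, 1) + rnorm(n)
  fit <- gwasGP:::remlSpectral(y, X, eig)
  v <- pmax(eig$values, 0) + fit$delta
  ty <- drop(crossprod(eig$vectors, y)); tX <- crossprod(eig$vectors, X)
  r <- ty - drop(tX %*% fit$beta)
  expect_lt(max(abs(crossprod(tX, r / v))), 1e-8) # GLS normal equations
})
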