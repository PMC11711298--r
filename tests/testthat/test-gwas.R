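gwasPanel <- function() {
  cachedPanel("gwasPanel", function() {
    sim <- structuredPanel()
    geno <- imputeMissing(sim$geno)
    kin <- computeGRM(geno)
    d <- dosageMatrix(geno)
    set.seed(77)
    qtl <- sample(ncol(d), 30)
    g <- drop(sweep(d[, qtl], 2, colMeans(d[, qtl])) %*% rnorm(30))
    y <- stats::setNames(g + rnorm(nrow(d), 0, stats::sd(g)), rownames(d))
    list(sim = sim, geno = geno, kin = kin, y = y, qtl = qtl)
  })
}

test_that("the Bonferroni threshold is alpha over the marker count", {
  expect_equal(bonferroniThreshold(77835, 0.05), 6.4238e-7, tolerance = 1e-4)
  expect_equal(bonferroniThreshold(100, 0.01), 1e-4)
  expect_equal(bonferroniThreshold(1, 0.05), 0.05)
  expect_error(bonferroniThreshold(0, 0.05), "nSnps")
  expect_error(bonferroniThreshold(10, 1.5), "alpha")
})

test_that("the mixed-model scan reports sound per-marker statistics", {
  p <- gwasPanel()
  scan <- mlmScan(p$y, p$geno, p$kin, nPcs = 3)
  tab <- gwasTable(scan)
  expect_equal(nrow(tab), nMarkers(p$geno))
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_equal(unname(gwasThresholds(scan)["5%"]), 0.05 / nrow(tab))
  # duplicated marker columns give identical test rows
  d <- dosageMatrix(p$geno)
  d2 <- cbind(d[, 1:50], dup = d[, 7])
  g2 <- asGeno(d2)
  kin2 <- computeGRM(g2)
  s2 <- mlmScan(p$y, g2, kin2)
  t2 <- gwasTable(s2)
  expect_equal(t2$p[51], t2$p[7], tolerance = 1e-12)
  expect_equal(t2$beta[51], t2$beta[7], tolerance = 1e-12)
})

test_that("p-values are invariant to affine phenotype transforms", {
  p <- gwasPanel()
  s1 <- mlmScan(p$y, p$geno, p$kin)
  s2 <- mlmScan(2.5 * p$y - 7, p$geno, p$kin)
  expect_lt(max(abs(gwasTable(s1)$p - gwasTable(s2)$p)), 1e-8)
})

test_that("constant marker columns are flagged with p = 1", {
  p <- gwasPanel()
  d <- dosageMatrix(p$geno)[, 1:30]
  d[, 5] <- 1
  g <- asGeno(d)
  # the kinship comes from the full panel; only accessions must match
  s <- mlmScan(p$y, g, p$kin)
  tab <- gwasTable(s)
  expect_equal(tab$p[5], 1)
  expect_equal(tab$flag[5], "constant")
})

test_that("forcing out the polygenic term reduces the scan to OLS", {
  p <- gwasPanel()
  scan <- mlmScan(p$y, p$geno, p$kin, nPcs = 3, delta = Inf)
  pcs <- pcaGenotypes(p$kin, 3)$scores
  d <- dosageMatrix(p$geno)
  # direct-regression oracle with the same large-sample normal test
  pOracle <- vapply(1:80, function(j) {
    fit <- stats::lm(p$y ~ pcs + d[, j])
    cf <- summary(fit)$coefficients
    z <- cf[nrow(cf), 1] / cf[nrow(cf), 2]
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  expect_lt(max(abs(pOracle - gwasTable(scan)$p[1:80])), 1e-6)
})

test_that("marker ranking follows min-p with deterministic ties", {
  mkTab <- function(p) {
    new("GwasResult",
        table = data.frame(chrom = "chr1", pos = 1:4, beta = 0, se = 1,
                           z = 0, p = p, flag = ""),
        trait = "t", phenoSet = "x", nPcs = 0L,
        thresholds = c("5%" = 0.05 / 4, "1%" = 0.01 / 4))
  }
  rA <- mkTab(c(0.5, 1e-6, 0.2, 0.9))
  rB <- mkTab(c(0.5, 0.9, 0.2, 1e-7))
  rk <- rankMarkers(list(rA, rB), 4)
  expect_equal(rk[1:2], c(4L, 2L)) # the two hits lead, in min-p order
  expect_setequal(rankMarkers(list(rA), 4), 1:4)
  expect_error(rankMarkers(list(rA), 5), "exceeds")
  expect_identical(rankMarkers(list(rA, rB), 3), rankMarkers(list(rA, rB), 3))
})

test_that("ranked markers are enriched near true QTLs", {
  fracs <- sapply(1:2, function(s) {
    cfg <- simGenotypeConfig(400, 4000, nChromosomes = 8, fstTarget = 0.2,
                             ldRho = 0.6, inbreeding = 0.9, seed = 401 + s)
    sim <- simulateGenotypes(cfg)
    d <- dosageMatrix(sim$geno)
    set.seed(501 + s)
    qtl <- sample(ncol(d), 10)
    g <- drop(sweep(d[, qtl], 2, colMeans(d[, qtl])) %*% rnorm(10))
    y <- stats::setNames(g + rnorm(nrow(d), 0, stats::sd(g)), rownames(d))
    scan <- mlmScan(y, sim$geno, computeGRM(sim$geno))
    top <- rankMarkers(list(scan), 100)
    mk <- markerInfo(sim$geno)
    nearQtl <- function(idx) {
      vapply(idx, function(j) any(mk$chrom[qtl] == mk$chrom[j] &
                                    abs(mk$pos[qtl] - mk$pos[j]) <= 50000),
             logical(1))
    }
    c(top = mean(nearQtl(top)), bg = mean(nearQtl(seq_len(ncol(d)))))
  })
  expect_gt(mean(fracs["top", ]), 5 * mean(fracs["bg", ]))
})

test_that("TAS counting de-duplicates across phenotype sets", {
  tab <- data.frame(chrom = "chr1", pos = 1:3, beta = 0, se = 1, z = 0,
                    p = c(1e-9, 0.5, 0.2), flag = "")
  r1 <- new("GwasResult", table = tab, trait = "t", phenoSet = "env1",
            nPcs = 0L, thresholds = c("5%" = 0.05 / 3, "1%" = 0.01 / 3))
  r2 <- new("GwasResult", table = tab, trait = "t", phenoSet = "env2",
            nPcs = 0L, thresholds = c("5%" = 0.05 / 3, "1%" = 0.01 / 3))
  out <- countTAS(list(r1, r2))
  expect_equal(out$count, 1L)
  expect_true(out$table$multiSet[1])
  expect_equal(unname(out$perSet), c(1L, 1L))
  none <- new("GwasResult", table = transform(tab, p = c(0.5, 0.6, 0.7)),
              trait = "t", phenoSet = "e", nPcs = 0L,
              thresholds = c("5%" = 0.05 / 3, "1%" = 0.01 / 3))
  expect_equal(countTAS(list(none))$count, 0L)
})

test_that("null scans yield TAS counts within the Bonferroni bound", {
  counts <- vapply(1:5, function(s) {
    cfg <- simGenotypeConfig(150, 2000, nChromosomes = 2, fstTarget = 0.2,
                             ldRho = 0.2, inbreeding = 0.9, seed = 800 + s)
    sim <- simulateGenotypes(cfg)
    geno <- sim$geno
    kin <- computeGRM(geno)
    set.seed(900 + s)
    scans <- lapply(1:3, function(i)
      mlmScan(namedPheno(geno, rnorm(150)), geno, kin, phenoSet = paste0("e", i)))
    countTAS(scans)$count
  }, integer(1))
  # 15 scans x 2000 SNPs at threshold 0.05/2000 -> expected ~0.75 in total
  expect_lte(sum(counts), 3)
})
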