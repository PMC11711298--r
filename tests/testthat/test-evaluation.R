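test_that("fold assignment balances sizes and reproduces the 80/20 split", {
  ids <- sprintf("a%03d", 1:195)
  f <- makeFolds(ids, 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(39L, 5))
  expect_equal(sum(f != 1), 156) # 80% training at n = 195
  f7 <- makeFolds(letters[1:7], 5, seed = 1)
  expect_equal(sort(as.integer(table(f7)), decreasing = TRUE), c(2L, 2L, 1L, 1L, 1L))
  expect_identical(makeFolds(ids, 5, seed = 9), makeFolds(ids, 5, seed = 9))
  expect_false(identical(makeFolds(ids, 5, seed = 9), makeFolds(ids, 5, seed = 10)))
  expect_error(makeFolds(letters[1:3], 5, seed = 1), "nFolds")
})

test_that("prediction metrics match their closed forms", {
  y <- c(1, 2, 3, 4)
  expect_equal(unname(gpMetrics(y, y)), c(1, 1, 0, 0))
  m2 <- gpMetrics(y, 2 * y)
  expect_equal(unname(m2["accuracy"]), 1)
  expect_equal(unname(m2["slope"]), 0.5)
  m3 <- gpMetrics(c(1, 2, 3, 4), c(1, 2, 3, 5))
  expect_equal(unname(m3["mse"]), 0.25)
  expect_equal(unname(m3["mae"]), 0.25)
  # hand arithmetic: cov = 6.5/3, var(yc) = 5/3, var(yp) = 8.75/3
  expect_equal(unname(m3["accuracy"]), 6.5 / sqrt(5 * 8.75), tolerance = 1e-12)
  expect_equal(unname(m3["slope"]), 6.5 / 8.75, tolerance = 1e-12)
  expect_error(gpMetrics(1:4, 1:5), "equal length")
  expect_error(gpMetrics(1:2, 1:2), "three")
  flat <- gpMetrics(y, rep(2, 4))
  expect_true(is.na(flat["accuracy"]) && is.na(flat["slope"]))
  expect_false(anyNA(flat[c("mse", "mae")]))
})

test_that("mae squared never exceeds mse", {
  set.seed(14)
  for (i in 1:20) {
    m <- gpMetrics(rnorm(30), rnorm(30))
    expect_lte(m["mae"]^2, m["mse"] + 1e-12)
  }
})

cvPanel <- function() {
  cachedPanel("cvPanel", function() {
    cfg <- simGenotypeConfig(120, 600, nChromosomes = 2, fstTarget = 0.2,
                             ldRho = 0.8, inbreeding = 0.9, seed = 61)
    sim <- simulateGenotypes(cfg)
    pcfg <- simPhenotypeConfig("T", 20, 0.7, seed = 62)
    ph <- simulatePhenotypes(sim$geno, sim$labels, pcfg)
    yc <- correctedPhenotypes(suppressWarnings(fitMultiEnvBlup(ph$trials)))[, 1]
    list(geno = sim$geno, yc = yc)
  })
}

test_that("the CV engine is deterministic and dimensionally complete", {
  p <- cvPanel()
  grids <- list(gblup = data.frame(), ridge = deskGrid("ridge"))
  r1 <- runCV(p$geno, p$yc, models = c("gblup", "ridge"), nFolds = 5,
              nRepeats = 2, tuningFolds = 3, seed = 5, grids = grids)
  r2 <- runCV(p$geno, p$yc, models = c("gblup", "ridge"), nFolds = 5,
              nRepeats = 2, tuningFolds = 3, seed = 5, grids = grids)
  expect_identical(cvCells(r1), cvCells(r2))
  cells <- cvCells(r1)
  expect_equal(nrow(cells), 2 * 2 * 5) # models x repeats x folds
  ok <- !cells$failed
  expect_true(all(abs(cells$accuracy[ok]) <= 1))
  expect_true(all(cells$mae[ok]^2 <= cells$mse[ok] + 1e-12))
  expect_error(runCV(p$geno, p$yc, models = character(0)), "at least one")
  expect_error(runCV(p$geno, p$yc, models = "forest"), "unknown model")
})

test_that("the all-marker sweep cell equals the plain CV baseline exactly", {
  p <- cvPanel()
  grids <- list(ridge = deskGrid("ridge"))
  base <- runCV(p$geno, p$yc, models = "ridge", nFolds = 5, nRepeats = 2,
                tuningFolds = 3, seed = 11, grids = grids)
  sw <- markerSubsetSweep(p$geno, p$yc, topGrid = c(50, 200),
                          mode = "whole_data", model = "ridge", nFolds = 5,
                          nRepeats = 2, tuningFolds = 3, seed = 11,
                          grids = grids)
  cellsB <- cvCells(base)
  cellsS <- cvCells(sw)
  allCells <- cellsS[cellsS$topN == "all", ]
  expect_equal(allCells$accuracy, cellsB$accuracy, tolerance = 1e-12)
  expect_equal(allCells$mse, cellsB$mse, tolerance = 1e-12)
  # report shape: one cell block per topN value plus the baseline
  expect_setequal(unique(cellsS$topN), c("50", "200", "all"))
  expect_warning(
    markerSubsetSweep(p$geno, p$yc, topGrid = c(50, 10000), mode = "whole_data",
                      model = "ridge", nFolds = 5, nRepeats = 1,
                      tuningFolds = 2, seed = 1, grids = grids),
    "exceeding")
})

test_that("reports are written reproducibly with a manifest", {
  p <- cvPanel()
  grids <- list(gblup = data.frame())
  r <- runCV(p$geno, p$yc, models = "gblup", nFolds = 4, nRepeats = 2,
             seed = 2, grids = grids, tuningFolds = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  paths1 <- writeReport(r, d1)
  paths2 <- writeReport(r, d2)
  expect_true(all(file.exists(paths1)))
  expect_identical(readLines(paths1["cells"]), readLines(paths2["cells"]))
  s <- utils::read.delim(paths1["summary"])
  expect_equal(nrow(s), 1)
  expect_match(readLines(paths1["manifest"]), "gwasGP", all = FALSE)
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)
  expect_error(writeReport(r, file.path(blocker, "sub")), "cannot create")
})

test_that("accuracy rises with heritability in the CV benchmark", {
  cfg <- simGenotypeConfig(150, 1000, nChromosomes = 2, fstTarget = 0.2,
                           ldRho = 0.8, inbreeding = 0.9, seed = 71)
  sim <- simulateGenotypes(cfg)
  accs <- vapply(c(0.25, 0.85), function(h2) {
    pcfg <- simPhenotypeConfig("T", 20, h2, seed = 72)
    ph <- simulatePhenotypes(sim$geno, sim$labels, pcfg)
    yc <- correctedPhenotypes(suppressWarnings(fitMultiEnvBlup(ph$trials)))[, 1]
    r <- runCV(sim$geno, yc, models = "gblup", nFolds = 5, nRepeats = 3,
               tuningFolds = 2, seed = 9, grids = list(gblup = data.frame()))
    cvSummary(r)$meanAccuracy
  }, numeric(1))
  expect_gt(accs[2], accs[1])
})
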