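#' Random cross-validation fold assignment
#'
#' A random permutation is split into `nFolds` near-equal parts (sizes differ
#' by at most one, larger folds first); each accession lands in exactly one
#' test fold. Deterministic given the seed.
#'
#' @param ids accession identifiers.
#' @param nFolds number of folds (`<=` number of accessions).
#' @param seed RNG seed.
#' @return named integer vector of fold ids (1..nFolds) per accession.
#' @export
makeFolds <- function(ids, nFolds, seed) {
  n <- length(ids)
  stopIfNot(nFolds >= 2 && nFolds <= n, "nFolds must lie in [2, n]")
  sizes <- rep(n %/% nFolds, nFolds)
  rem <- n %% nFolds
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  perm <- withSeed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(nFolds), sizes)
  names(fold) <- ids
  fold
}

#' Prediction-quality metrics for one test fold
#'
#' `accuracy` is the Pearson correlation of observed corrected phenotypes
#' `y_c` and predictions `y_p`; the unbiasedness `slope` is the regression
#' coefficient of observed on predicted, `cov(y_c, y_p)/var(y_p)`; `mse` and
#' `mae` are the mean squared and mean absolute differences over the test
#' individuals. Accuracy and slope are `NA` when the predictions are
#' constant.
#'
#' @param yc observed corrected phenotypes (length >= 3).
#' @param yp predictions, same length.
#' @return named numeric vector `(accuracy, slope, mse, mae)`.
#' @export
gpMetrics <- function(yc, yp) {
  stopIfNot(length(yc) == length(yp), "yc and yp must have equal length")
  stopIfNot(length(yc) >= 3, "metrics need at least three observations")
  vp <- stats::var(yp)
  degenerate <- !is.finite(vp) || vp == 0
  c(accuracy = if (degenerate) NA_real_ else stats::cor(yc, yp),
    slope = if (degenerate) NA_real_ else stats::cov(yc, yp) / vp,
    mse = mean((yc - yp)^2),
    mae = mean(abs(yc - yp)))
}

# ---- internal tuning machinery ------------------------------------------

# multi-lambda kernel ridge predictions through one eigendecomposition
kernelRidgeMulti <- function(Ktt, Kpt, y, lambdas) {
  e <- eigen(Ktt, symmetric = TRUE)
  yc <- y - mean(y)
  uy <- drop(crossprod(e$vectors, yc))
  sapply(lambdas, function(l) {
    a <- e$vectors %*% (uy / (pmax(e$values, 0) + l))
    drop(Kpt %*% a) + mean(y)
  })
}

.innerScore <- function(pred, obs) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(pred, obs)
}

# grid rows ordered so that, on score ties, the earlier (simpler / smaller
# penalty) candidate wins via which.max
.orderGrid <- function(g) {
  cols <- intersect(c("degree", "r", "gamma", "C", "epsilon",
                      "l1_fraction", "lambda", "lambdaRel"), names(g))
  if (!length(cols) || !nrow(g)) return(g)
  g[do.call(order, g[cols]), , drop = FALSE]
}

.tuneRidge <- function(fd, yTr, grid, innerId) {
  grid <- .orderGrid(grid)
  lams <- if ("lambdaRel" %in% names(grid)) {
    d1 <- eigen(fd$gramTr, symmetric = TRUE, only.values = TRUE)$values[1]
    grid$lambdaRel * d1
  } else grid$lambda
  nInner <- max(innerId)
  scores <- matrix(NA_real_, length(lams), nInner)
  for (f in seq_len(nInner)) {
    itr <- which(innerId != f); ite <- which(innerId == f)
    preds <- kernelRidgeMulti(fd$gramTr[itr, itr], fd$gramTr[ite, itr, drop = FALSE],
                              yTr[itr], lams)
    scores[, f] <- apply(preds, 2, .innerScore, obs = yTr[ite])
  }
  best <- which.max(rowMeans(scores, na.rm = TRUE))
  pred <- kernelRidgeMulti(fd$gramTr, fd$gramTeTr, yTr, lams[best])[, 1]
  list(pred = pred, hyper = list(lambda = lams[best]))
}

.tuneKrr <- function(fd, yTr, grid, innerId) {
  grid <- .orderGrid(grid)
  key <- paste(grid$gamma, grid$r, grid$degree)
  nInner <- max(innerId)
  best <- NULL; bestScore <- -Inf
  p <- ncol(fd$XsTr)
  for (ck in unique(key)) {
    sub <- grid[key == ck, , drop = FALSE]
    gamma <- sub$gamma[1]; if (is.na(gamma)) gamma <- 1 / p
    r <- sub$r[1]; degree <- sub$degree[1]
    K <- applyKernel(fd$gramTr, "poly", gamma, r, degree, fd$selfTr, fd$selfTr)
    lams <- if ("lambdaRel" %in% names(sub)) {
      d1 <- eigen(K, symmetric = TRUE, only.values = TRUE)$values[1]
      sub$lambdaRel * d1
    } else sub$lambda
    scores <- matrix(NA_real_, length(lams), nInner)
    for (f in seq_len(nInner)) {
      itr <- which(innerId != f); ite <- which(innerId == f)
      preds <- kernelRidgeMulti(K[itr, itr], K[ite, itr, drop = FALSE], yTr[itr], lams)
      scores[, f] <- apply(preds, 2, .innerScore, obs = yTr[ite])
    }
    sc <- rowMeans(scores, na.rm = TRUE)
    if (any(is.finite(sc)) && max(sc, na.rm = TRUE) > bestScore) {
      i <- which.max(sc)
      bestScore <- max(sc, na.rm = TRUE)
      best <- list(gamma = gamma, r = r, degree = degree, lambda = lams[i], K = K)
    }
  }
  Kte <- applyKernel(fd$gramTeTr, "poly", best$gamma, best$r, best$degree,
                     fd$selfTe, fd$selfTr)
  pred <- kernelRidgeMulti(best$K, Kte, yTr, best$lambda)[, 1]
  list(pred = pred,
       hyper = best[c("lambda", "gamma", "r", "degree")])
}

.tuneEnet <- function(fd, yTr, grid, innerId, alphaFixed = NULL) {
  grid <- .orderGrid(grid)
  alphas <- if (!is.null(alphaFixed)) alphaFixed else unique(grid$l1_fraction)
  ycTr <- yTr - mean(yTr)
  lmax <- max(abs(crossprod(fd$XsTr, ycTr)))
  lams <- if ("lambdaRel" %in% names(grid)) unique(grid$lambdaRel) * lmax
          else unique(grid$lambda)
  lams <- sort(lams, decreasing = TRUE)
  # tolerances scale with the phenotype so tuning cost is invariant to units;
  # tuning fits may stop at the sweep cap (their iterate is still a good
  # selector), the final refit runs to full convergence when it can
  sdy <- max(stats::sd(yTr), .Machine$double.eps)
  tolTune <- 1e-4 * sdy
  nInner <- max(innerId)
  best <- NULL; bestScore <- -Inf
  for (a in alphas) {
    scores <- matrix(NA_real_, length(lams), nInner)
    for (f in seq_len(nInner)) {
      itr <- which(innerId != f); ite <- which(innerId == f)
      fit <- cdEnetPath(fd$XsTr[itr, , drop = FALSE], yTr[itr], lams, a,
                        tolTune, 500L)
      preds <- fd$XsTr[ite, , drop = FALSE] %*% fit$beta
      preds <- sweep(preds, 2, fit$b0, "+")
      scores[, f] <- apply(preds, 2, .innerScore, obs = yTr[ite])
    }
    sc <- rowMeans(scores, na.rm = TRUE)
    if (any(is.finite(sc)) && max(sc, na.rm = TRUE) > bestScore) {
      # among exact score ties keep the smallest lambda
      top <- which(sc == max(sc, na.rm = TRUE))
      i <- top[which.min(lams[top])]
      bestScore <- max(sc, na.rm = TRUE)
      best <- list(l1_fraction = a, lambda = lams[i])
    }
  }
  if (is.null(best)) stop("elastic-net tuning failed on every grid point", call. = FALSE)
  path <- lams[lams >= best$lambda]
  fit <- cdEnetPath(fd$XsTr, yTr, path, best$l1_fraction, 3e-5 * sdy, 1000L)
  k <- length(path)
  pred <- drop(fd$XsTe %*% fit$beta[, k]) + fit$b0[k]
  list(pred = pred, hyper = best)
}

.tuneSvr <- function(fd, yTr, grid, innerId, linear) {
  grid <- .orderGrid(grid)
  nInner <- max(innerId)
  p <- ncol(fd$XsTr)
  best <- NULL; bestScore <- -Inf
  kernCache <- list()
  # standardized phenotype so C and epsilon are scale-free (accuracy is
  # unaffected by the final rescaling, so tuning can stay on this scale)
  yCtr <- mean(yTr); ySc <- max(stats::sd(yTr), .Machine$double.eps)
  ys <- (yTr - yCtr) / ySc
  for (gi in seq_len(nrow(grid))) {
    gamma <- if (linear) NA else { g <- grid$gamma[gi]; if (is.na(g)) 1 / p else g }
    r <- if (linear) NA else grid$r[gi]
    degree <- if (linear) NA else grid$degree[gi]
    key <- paste(gamma, r, degree)
    if (is.null(kernCache[[key]]))
      kernCache[[key]] <- if (linear) fd$gramTr else
        applyKernel(fd$gramTr, "poly", gamma, r, degree, fd$selfTr, fd$selfTr)
    K <- kernCache[[key]]
    sc <- numeric(nInner)
    for (f in seq_len(nInner)) {
      itr <- which(innerId != f); ite <- which(innerId == f)
      m <- tryCatch(
        kernlab::ksvm(kernlab::as.kernelMatrix(K[itr, itr]), ys[itr],
                      type = "eps-svr", C = grid$C[gi], epsilon = grid$epsilon[gi]),
        error = function(e) NULL)
      if (is.null(m)) { sc[f] <- NA; next }
      sv <- kernlab::SVindex(m)
      pr <- predict(m, kernlab::as.kernelMatrix(K[ite, itr, drop = FALSE][, sv, drop = FALSE]))
      sc[f] <- .innerScore(drop(pr), ys[ite])
    }
    msc <- mean(sc, na.rm = TRUE)
    if (is.finite(msc) && msc > bestScore) {
      bestScore <- msc
      best <- list(C = grid$C[gi], epsilon = grid$epsilon[gi],
                   gamma = gamma, r = r, degree = degree, K = K)
    }
  }
  if (is.null(best)) stop("SVR tuning failed on every grid point", call. = FALSE)
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(best$K), ys, type = "eps-svr",
                     C = best$C, epsilon = best$epsilon)
  Kte <- if (linear) fd$gramTeTr else
    applyKernel(fd$gramTeTr, "poly", best$gamma, best$r, best$degree,
                fd$selfTe, fd$selfTr)
  sv <- kernlab::SVindex(m)
  pred <- yCtr + ySc *
    drop(predict(m, kernlab::as.kernelMatrix(Kte[, sv, drop = FALSE])))
  hyper <- best[c("C", "epsilon", "gamma", "r", "degree")]
  if (linear) hyper <- hyper[c("C", "epsilon")]
  list(pred = pred, hyper = hyper)
}

.gblupFit <- function(fdRaw, yTr) {
  eig <- eigen(fdRaw$Gtt, symmetric = TRUE)
  delta <- remlSpectral(yTr, matrix(1, length(yTr)), eig)$delta
  mu <- mean(yTr)
  uy <- drop(crossprod(eig$vectors, yTr - mu))
  a <- eig$vectors %*% (uy / (pmax(eig$values, 0) + delta))
  list(pred = drop(fdRaw$GteTr %*% a) + mu, hyper = list(lambdaG = delta))
}

# build fold data for one column set
.foldData <- function(D, tr, te, cols, needStd, needRaw) {
  fd <- list()
  if (needStd) {
    std <- standardizeTrain(D[tr, cols, drop = FALSE])
    fd$XsTr <- std$X
    fd$XsTe <- applyStandardize(D[te, cols, drop = FALSE], std)
    fd$gramTr <- tcrossprod(fd$XsTr)
    fd$gramTeTr <- fd$XsTe %*% t(fd$XsTr)
    fd$selfTr <- rowSums(fd$XsTr^2)
    fd$selfTe <- rowSums(fd$XsTe^2)
  }
  if (needRaw) {
    vr <- vanRadenParts(D[tr, cols, drop = FALSE])
    fd$Gtt <- tcrossprod(vr$Wc) / vr$cst
    fd$GteTr <- tcrossprod(sweep(D[te, cols, drop = FALSE], 2, 2 * vr$p), vr$Wc) / vr$cst
  }
  fd
}

.runModelOnFold <- function(fam, fd, yTr, grid, innerId) {
  switch(fam,
    gblup = .gblupFit(fd, yTr),
    ridge = .tuneRidge(fd, yTr, grid, innerId),
    krr = .tuneKrr(fd, yTr, grid, innerId),
    lasso = .tuneEnet(fd, yTr, grid, innerId, alphaFixed = 1),
    elasticnet = .tuneEnet(fd, yTr, grid, innerId),
    svr_linear = .tuneSvr(fd, yTr, grid, innerId, linear = TRUE),
    svr_poly = .tuneSvr(fd, yTr, grid, innerId, linear = FALSE),
    stop("unknown model family: ", fam, call. = FALSE))
}

#' Repeated cross-validation benchmark of prediction models
#'
#' Per repetition, accessions are split into `nFolds` random folds; per fold,
#' every model family is tuned by grid search with an internal
#' `tuningFolds`-fold cross-validation on the training portion only (selected
#' by mean internal accuracy; ties favour the simpler candidate), refit on
#' the whole training fold, and evaluated with [gpMetrics()] on the held-out
#' fold. All randomness derives from `seed` through a hierarchical scheme
#' (repeat index -> fold seed; fold index -> tuning seed), so adding a model
#' or trait never perturbs the splits. A model family failing on a fold is
#' recorded as a failed cell and the run continues.
#'
#' @param geno missing-free [GenotypeMatrix] or dosage matrix.
#' @param yc named numeric vector (one trait) or accessions x traits matrix
#'   of corrected phenotypes.
#' @param models character vector of model families to compare.
#' @param nFolds,nRepeats,tuningFolds,seed cross-validation configuration.
#' @param grids named list (family -> data.frame) of tuning grids; defaults
#'   to [defaultGrid()] per family; [deskGrid()] gives desk-scale grids.
#' @return a [CVReport].
#' @export
runCV <- function(geno, yc, models = .gpFamilies, nFolds = 5, nRepeats = 20,
                  tuningFolds = 5, seed = 1, grids = NULL) {
  stopIfNot(length(models) >= 1, "models must name at least one family")
  stopIfNot(all(models %in% .gpFamilies),
            paste("unknown model families:",
                  paste(setdiff(models, .gpFamilies), collapse = ", ")))
  D <- if (is(geno, "GenotypeMatrix")) dosageMatrix(geno) else geno
  stopIfNot(!anyNA(D), "runCV requires an imputed (missing-free) matrix")
  if (is.vector(yc)) yc <- matrix(yc, ncol = 1,
                                  dimnames = list(names(yc), "trait"))
  if (!is.null(rownames(yc)) && !is.null(rownames(D))) {
    stopIfNot(all(rownames(D) %in% rownames(yc)), "yc must cover all accessions")
    yc <- yc[rownames(D), , drop = FALSE]
  }
  stopIfNot(nrow(yc) == nrow(D), "yc rows must match accessions")
  if (is.null(grids)) grids <- stats::setNames(
    lapply(models, defaultGrid, nSnps = ncol(D)), models)

  cells <- .cvEngine(D, yc, models, nFolds, nRepeats, tuningFolds, seed, grids)
  new("CVReport", cells = cells,
      config = list(models = models, nFolds = nFolds, nRepeats = nRepeats,
                    tuningFolds = tuningFolds, seed = seed,
                    nAccessions = nrow(D), nMarkers = ncol(D)))
}

.cvEngine <- function(D, yc, models, nFolds, nRepeats, tuningFolds, seed, grids,
                      columnSets = NULL, mode = NULL) {
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(D)))
  needStd <- any(models != "gblup")
  needRaw <- "gblup" %in% models
  out <- list()
  for (r in seq_len(nRepeats)) {
    fold <- makeFolds(ids, nFolds, childSeed(seed, r, salt = 1L))
    for (f in seq_len(nFolds)) {
      tr <- which(fold != f); te <- which(fold == f)
      innerId <- makeFolds(ids[tr], tuningFolds, childSeed(seed, r, salt = 100L + f))
      sets <- if (is.null(columnSets)) list(all = seq_len(ncol(D)))
              else columnSets(tr, r, f)
      for (sn in names(sets)) {
        cols <- sets[[sn]]
        fd <- .foldData(D, tr, te, cols, needStd, needRaw)
        for (t in seq_len(ncol(yc))) {
          yTr <- yc[tr, t]; yTe <- yc[te, t]
          for (fam in models) {
            res <- tryCatch(
              .runModelOnFold(fam, fd, yTr, grids[[fam]], innerId),
              error = function(e) e)
            if (inherits(res, "error")) {
              row <- data.frame(trait = colnames(yc)[t], model = fam,
                                rep = r, fold = f,
                                accuracy = NA_real_, slope = NA_real_,
                                mse = NA_real_, mae = NA_real_,
                                hyper = "", failed = TRUE,
                                stringsAsFactors = FALSE)
            } else {
              m <- gpMetrics(yTe, res$pred)
              row <- data.frame(trait = colnames(yc)[t], model = fam,
                                rep = r, fold = f,
                                accuracy = m["accuracy"], slope = m["slope"],
                                mse = m["mse"], mae = m["mae"],
                                hyper = paste(names(res$hyper),
                                              signif(unlist(res$hyper), 4),
                                              sep = "=", collapse = ";"),
                                failed = FALSE, stringsAsFactors = FALSE)
            }
            if (!is.null(columnSets)) { row$topN <- sn; row$mode <- mode }
            out[[length(out) + 1L]] <- row
          }
        }
      }
    }
  }
  cells <- do.call(rbind, out)
  rownames(cells) <- NULL
  cells
}

#' Aggregate a cross-validation report
#'
#' Mean and standard deviation of each metric over folds x repeats, per
#' trait and model (and per marker subset for sweep reports).
#'
#' @param report a [CVReport] or [SweepReport].
#' @return data.frame of aggregates.
#' @export
cvSummary <- function(report) {
  cells <- report@cells
  by <- intersect(c("trait", "model", "topN", "mode"), names(cells))
  groups <- split(cells, cells[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    ok <- !g$failed
    data.frame(g[1, by, drop = FALSE],
               meanAccuracy = mean(g$accuracy[ok], na.rm = TRUE),
               sdAccuracy = stats::sd(g$accuracy[ok], na.rm = TRUE),
               meanSlope = mean(g$slope[ok], na.rm = TRUE),
               meanMse = mean(g$mse[ok], na.rm = TRUE),
               meanMae = mean(g$mae[ok], na.rm = TRUE),
               nCells = sum(ok), failures = sum(!ok),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' GWAS-derived top-N marker-subset sweep
#'
#' Evaluates prediction accuracy using only the top-N GWAS-ranked markers,
#' over a grid of N, against the all-marker baseline under identical folds.
#' Two ranking modes are provided:
#' \describe{
#'   \item{within_fold}{(default, leakage-safe) the association scan and
#'     marker ranking are recomputed on each training fold only, so no
#'     test-fold accession ever informs marker selection.}
#'   \item{whole_data}{the ranking is computed once from a scan on all
#'     accessions and the cross-validation then runs on the fixed subset.
#'     This reproduces the common published procedure but is optimistically
#'     biased, and the report flags it as such.}
#' }
#'
#' @param geno missing-free [GenotypeMatrix].
#' @param yc named numeric vector of corrected phenotypes for the predicted
#'   trait.
#' @param rankPhenos matrix (accessions x phenotype sets) used for the
#'   association ranking via minimum p-value across sets; defaults to `yc`
#'   alone.
#' @param topGrid strictly increasing marker counts to evaluate.
#' @param mode "within_fold" or "whole_data".
#' @param model the single model family evaluated across the sweep (the
#'   best-performing family from an all-marker comparison is the intended
#'   input).
#' @param nFolds,nRepeats,tuningFolds,seed as in [runCV()]; with equal seeds
#'   the "all" cells match the [runCV()] baseline exactly.
#' @param grids named list of tuning grids (default [deskGrid()] for the
#'   chosen family).
#' @param nPcs principal components used in the ranking scans.
#' @return a [SweepReport].
#' @export
markerSubsetSweep <- function(geno, yc, rankPhenos = NULL,
                              topGrid = c(100, 500, 1000, 3000, 5000),
                              mode = c("within_fold", "whole_data"),
                              model = "ridge", nFolds = 5, nRepeats = 10,
                              tuningFolds = 5, seed = 1, grids = NULL,
                              nPcs = 3L) {
  mode <- match.arg(mode)
  D <- if (is(geno, "GenotypeMatrix")) dosageMatrix(geno) else geno
  stopIfNot(!anyNA(D), "markerSubsetSweep requires an imputed matrix")
  stopIfNot(!is.unsorted(topGrid, strictly = TRUE), "topGrid must be strictly increasing")
  if (!is.null(names(yc))) yc <- yc[rownames(D)]
  if (is.null(rankPhenos)) rankPhenos <- matrix(yc, ncol = 1,
                                                dimnames = list(rownames(D), "BLUP"))
  keepTop <- topGrid[topGrid <= ncol(D)]
  if (length(keepTop) < length(topGrid))
    warning("dropping topN values exceeding the marker count", call. = FALSE)
  topGrid <- keepTop
  maxTop <- max(topGrid)
  mk <- if (is(geno, "GenotypeMatrix")) markerInfo(geno)
        else data.frame(chrom = "chr0", pos = seq_len(ncol(D)))

  rankFromScan <- function(rows) {
    sub <- D[rows, , drop = FALSE]
    vr <- vanRadenParts(sub)
    G <- tcrossprod(vr$Wc) / vr$cst
    dimnames(G) <- list(rownames(sub), rownames(sub))
    kin <- new("KinshipMatrix", values = G, scalingConstant = vr$cst,
               alleleFreqs = vr$p)
    gm <- GenotypeMatrix(sub, mk)
    scans <- lapply(seq_len(ncol(rankPhenos)), function(s)
      mlmScan(rankPhenos[rows, s], gm, kin, nPcs = nPcs,
              phenoSet = colnames(rankPhenos)[s]))
    rankMarkers(scans, maxTop)
  }

  fixedRank <- if (mode == "whole_data") rankFromScan(seq_len(nrow(D))) else NULL
  columnSets <- function(tr, r, f) {
    rk <- if (mode == "whole_data") fixedRank else rankFromScan(tr)
    sets <- lapply(topGrid, function(tn) sort(rk[seq_len(tn)]))
    names(sets) <- as.character(topGrid)
    c(sets, list(all = seq_len(ncol(D))))
  }

  if (is.null(grids))
    grids <- stats::setNames(list(deskGrid(model)), model)
  ycMat <- matrix(yc, ncol = 1, dimnames = list(rownames(D), "trait"))
  cells <- .cvEngine(D, ycMat, model, nFolds, nRepeats, tuningFolds, seed,
                     grids, columnSets = columnSets, mode = mode)
  new("SweepReport", cells = cells,
      config = list(model = model, topGrid = topGrid, mode = mode,
                    nFolds = nFolds, nRepeats = nRepeats, seed = seed,
                    biasNote = if (mode == "whole_data")
                      "whole-data ranking is optimistically biased" else ""))
}

#' Write benchmark reports to tidy TSV files with a run manifest
#'
#' Writes `cells.tsv` (per-fold metrics), `summary.tsv` (aggregates) and
#' `manifest.txt` (configuration, seed, package and R versions, input
#' checksum) to `dir`. Re-running with an identical configuration and seed
#' reproduces identical bytes.
#'
#' @param report a [CVReport] or [SweepReport].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  cellsPath <- file.path(dir, "cells.tsv")
  sumPath <- file.path(dir, "summary.tsv")
  manPath <- file.path(dir, "manifest.txt")
  utils::write.table(report@cells, cellsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cvSummary(report), sumPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- report@config
  lines <- c(
    paste0("class: ", class(report)),
    paste0("package: gwasGP ", as.character(utils::packageVersion("gwasGP"))),
    paste0("R: ", R.version.string),
    vapply(names(cfg), function(k)
      paste0(k, ": ", paste(format(cfg[[k]]), collapse = ",")), character(1)))
  writeLines(lines, manPath)
  invisible(c(cells = cellsPath, summary = sumPath, manifest = manPath))
}
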