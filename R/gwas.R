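#' Mixed-linear-model association scan (P3D/EMMAX scheme)
#'
#' Variance components are estimated once under the null model (intercept,
#' the first `nPcs` principal components of the kinship, and a polygenic
#' effect with covariance proportional to the kinship) by spectral REML; the
#' implied whitening is then applied to the phenotype, covariates and every
#' marker column, and per-SNP effects are estimated by generalized least
#' squares with a two-sided Wald test against Normal(0, 1).
#'
#' @param yc named numeric vector of corrected phenotypes (one per accession).
#' @param geno missing-free [GenotypeMatrix] or dosage matrix.
#' @param kinship a [KinshipMatrix] from [computeGRM()], matching accessions.
#' @param nPcs number of kinship PCs as fixed covariates (default 3).
#' @param delta optional fixed variance ratio `sigma2e/sigma2g`; `NULL`
#'   (default) estimates it by REML, `Inf` drops the polygenic term and
#'   reduces the scan to ordinary least squares with PCs.
#' @param trait,phenoSet labels recorded in the result.
#' @return a [GwasResult] with per-SNP effect, standard error, Wald statistic
#'   and p-value, plus 5% and 1% Bonferroni thresholds (`alpha / n_snps`).
#'   Constant marker columns are reported with `p = 1` and flag "constant".
#' @export
mlmScan <- function(yc, geno, kinship, nPcs = 3L, delta = NULL,
                    trait = "trait", phenoSet = "BLUP") {
  d <- if (is(geno, "GenotypeMatrix")) dosageMatrix(geno) else geno
  mk <- if (is(geno, "GenotypeMatrix")) markerInfo(geno)
        else data.frame(chrom = "chr0", pos = seq_len(ncol(d)))
  stopIfNot(!anyNA(d), "mlmScan requires a missing-free matrix")
  G <- kinshipValues(kinship)
  stopIfNot(identical(rownames(G), rownames(d)),
            "kinship accessions do not match the genotype matrix")
  if (!is.null(names(yc))) yc <- yc[rownames(d)]
  stopIfNot(length(yc) == nrow(d), "yc must hold one value per accession")
  n <- nrow(d)
  # standardize the phenotype so the scan is exactly invariant to affine
  # transforms of yc; effects are reported back on the original scale
  yScale <- stats::sd(yc)
  stopIfNot(is.finite(yScale) && yScale > 0, "yc must not be constant")
  yc <- (yc - mean(yc)) / yScale

  eig <- eigen(G, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  pcs <- sweep(eig$vectors[, seq_len(nPcs), drop = FALSE], 2,
               sqrt(ev[seq_len(nPcs)]), "*")
  X0 <- cbind(`(Intercept)` = 1, pcs)

  if (is.null(delta)) {
    # tight search tolerance keeps the P3D weights (and hence p-values)
    # reproducible to ~1e-10 across affine phenotype representations
    fit <- remlSpectral(yc, X0, eig, tol = 1e-10)
    delta <- fit$delta
  }
  if (is.infinite(delta)) {
    sw <- rep(1, n)
  } else {
    sw <- 1 / sqrt(ev + delta)
  }
  Ut <- t(eig$vectors)
  yt <- sw * drop(Ut %*% yc)
  X0t <- sw * (Ut %*% X0)
  Wt <- sw * (Ut %*% d)

  qrX <- qr(X0t)
  My <- qr.resid(qrX, yt)
  MW <- qr.resid(qrX, Wt)
  xx <- colSums(MW^2)
  xy <- drop(crossprod(MW, My))
  yy <- sum(My^2)
  dfres <- n - ncol(X0t) - 1L
  const <- xx < 1e-12 * max(xx, 1)
  beta <- ifelse(const, NA_real_, xy / xx)
  rss <- pmax(yy - ifelse(const, 0, beta^2 * xx), 0)
  se <- ifelse(const, NA_real_, sqrt(rss / dfres / xx))
  z <- beta / se
  p <- ifelse(const, 1, 2 * stats::pnorm(-abs(z)))
  p <- pmax(p, .Machine$double.xmin) # keep p in (0, 1]

  tab <- data.frame(chrom = mk$chrom, pos = mk$pos,
                    beta = beta * yScale, se = se * yScale,
                    z = z, p = p,
                    flag = ifelse(const, "constant", ""),
                    stringsAsFactors = FALSE)
  thr <- c("5%" = bonferroniThreshold(nrow(tab), 0.05),
           "1%" = bonferroniThreshold(nrow(tab), 0.01))
  new("GwasResult", table = tab, trait = trait, phenoSet = phenoSet,
      nPcs = as.integer(nPcs), thresholds = thr)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param nSnps number of markers tested.
#' @param alpha family-wise error rate.
#' @return `alpha / nSnps`.
#' @export
bonferroniThreshold <- function(nSnps, alpha = 0.05) {
  stopIfNot(nSnps >= 1, "nSnps must be >= 1")
  stopIfNot(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  alpha / nSnps
}

#' Rank markers by minimum p-value across phenotype sets
#'
#' Takes, per SNP, the minimum p-value across the supplied scans (typically
#' the per-environment phenotypes plus their BLUP), sorts ascending with ties
#' broken by (chrom, pos), and returns the first `topN` marker indices.
#'
#' @param results list of [GwasResult] objects sharing one marker panel.
#' @param topN number of markers to return (`<=` panel size).
#' @return integer vector of marker column indices, best first.
#' @export
rankMarkers <- function(results, topN) {
  if (is(results, "GwasResult")) results <- list(results)
  tabs <- lapply(results, gwasTable)
  m <- nrow(tabs[[1]])
  for (tb in tabs)
    stopIfNot(nrow(tb) == m && all(tb$chrom == tabs[[1]]$chrom) &&
                all(tb$pos == tabs[[1]]$pos),
              "all results must share the same marker panel")
  stopIfNot(topN <= m, "topN exceeds the number of markers")
  minp <- do.call(pmin, c(lapply(tabs, `[[`, "p"), list(na.rm = TRUE)))
  ord <- order(minp, tabs[[1]]$chrom, tabs[[1]]$pos)
  ord[seq_len(topN)]
}

#' Count trait-associated SNPs across phenotype sets
#'
#' SNPs passing each scan's own Bonferroni threshold at `alpha` are collected
#' and de-duplicated across phenotype sets, with per-set membership flags so
#' that multi-environment associations can be reported.
#'
#' @param results list of [GwasResult] objects (may span traits).
#' @param alpha family-wise rate for the Bonferroni cut (default 0.05).
#' @return list with `count` (unique TASs), `table` (chrom, pos, sets,
#'   nSets, multiSet), and `perSet` (named counts per scan).
#' @export
countTAS <- function(results, alpha = 0.05) {
  if (is(results, "GwasResult")) results <- list(results)
  hits <- lapply(results, function(res) {
    tb <- gwasTable(res)
    thr <- bonferroniThreshold(nrow(tb), alpha)
    sel <- which(tb$p < thr)
    if (!length(sel)) return(NULL)
    data.frame(chrom = tb$chrom[sel], pos = tb$pos[sel],
               set = paste0(res@trait, "/", res@phenoSet),
               stringsAsFactors = FALSE)
  })
  perSet <- vapply(seq_along(results), function(i)
    if (is.null(hits[[i]])) 0L else nrow(hits[[i]]), integer(1))
  names(perSet) <- vapply(results, function(r) paste0(r@trait, "/", r@phenoSet),
                          character(1))
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    return(list(count = 0L,
                table = data.frame(chrom = character(0), pos = numeric(0),
                                   sets = character(0), nSets = integer(0),
                                   multiSet = logical(0)),
                perSet = perSet))
  key <- paste(hits$chrom, hits$pos)
  agg <- lapply(split(seq_len(nrow(hits)), key), function(ii) {
    data.frame(chrom = hits$chrom[ii[1]], pos = hits$pos[ii[1]],
               sets = paste(sort(unique(hits$set[ii])), collapse = ","),
               nSets = length(unique(hits$set[ii])),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, agg)
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  tab$multiSet <- tab$nSets > 1
  list(count = nrow(tab), table = tab, perSet = perSet)
}
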