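#' VanRaden method-1 genomic relationship matrix
#'
#' `G = W W' / (2 * sum(p_j (1 - p_j)))` with `W` the dosage matrix centred by
#' `2 p_j`; allele frequencies are estimated from the supplied matrix itself.
#' Column centring implies `G` has zero row sums and is positive semidefinite.
#'
#' @param geno a missing-free [GenotypeMatrix] or plain dosage matrix with at
#'   least two accessions and no monomorphic SNPs.
#' @return a [KinshipMatrix].
#' @export
computeGRM <- function(geno) {
  d <- if (is(geno, "GenotypeMatrix")) dosageMatrix(geno) else geno
  stopIfNot(!anyNA(d), "computeGRM requires a missing-free matrix; run imputeMissing")
  stopIfNot(nrow(d) >= 2, "computeGRM requires at least two accessions")
  p <- colMeans(d) / 2
  if (any(p == 0 | p == 1))
    stop("monomorphic SNP column(s) present; filter them out first", call. = FALSE)
  W <- sweep(d, 2, 2 * p)
  cst <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / cst
  dimnames(G) <- list(rownames(d), rownames(d))
  new("KinshipMatrix", values = G, scalingConstant = cst, alleleFreqs = p)
}

#' Principal components of the genomic relationship matrix
#'
#' Eigendecomposition of the VanRaden GRM (equivalent to an SVD of the
#' centred dosage matrix). Scores are eigenvectors scaled by the square root
#' of their eigenvalues; explained-variance fractions are eigenvalues over the
#' trace and are non-increasing.
#'
#' @param geno a missing-free [GenotypeMatrix], plain dosage matrix, or a
#'   precomputed [KinshipMatrix].
#' @param nComponents number of components, `< min(nAccessions, nMarkers)`.
#' @return list with `scores` (accessions x components) and
#'   `varianceExplained` (fractions).
#' @export
pcaGenotypes <- function(geno, nComponents = 10L) {
  stopIfNot(nComponents > 0, "nComponents must be positive")
  G <- if (is(geno, "KinshipMatrix")) kinshipValues(geno)
       else kinshipValues(computeGRM(geno))
  stopIfNot(nComponents < nrow(G), "nComponents must be < number of accessions")
  e <- eigen(G, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  k <- seq_len(nComponents)
  scores <- sweep(e$vectors[, k, drop = FALSE], 2, sqrt(ev[k]), "*")
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", k)
  list(scores = scores, varianceExplained = ev[k] / sum(ev))
}

#' Weir-Cockerham fixation index, per SNP and in windows
#'
#' Weir & Cockerham (1984) variance components for `r` subpopulations with
#' the random-union-of-gametes heterozygosity correction: per SNP,
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals) are computed from subpopulation sample sizes,
#' allele frequencies and observed heterozygote fractions; per-SNP
#' `theta = a / (a + b + c)` (may be negative). Window and overall estimates
#' are ratio-of-sums (`sum(a) / sum(a + b + c)`) over contributing SNPs, never
#' means of ratios. Windows are non-overlapping tiles from position 1.
#'
#' @param geno a [GenotypeMatrix] (missing calls allowed; excluded per SNP) or
#'   dosage matrix with marker metadata attached via a `markers` attribute.
#' @param labels subpopulation labels per accession (named or in row order);
#'   every subpopulation needs at least two members.
#' @param windowBp window width in bp (default 30000).
#' @return an [FstResult].
#' @export
weirCockerhamFst <- function(geno, labels, windowBp = 30000) {
  d <- dosageMatrix(geno)
  mk <- markerInfo(geno)
  if (!is.null(names(labels))) labels <- labels[rownames(d)]
  labels <- as.character(labels)
  pops <- sort(unique(labels))
  r <- length(pops)
  stopIfNot(r >= 2, "need at least two subpopulations")
  if (any(table(labels) < 2))
    stop("every subpopulation needs at least two accessions", call. = FALSE)

  # per-pop per-SNP sample sizes, allele freqs, het fractions (non-missing)
  nMat <- pMat <- hMat <- matrix(0, r, ncol(d))
  for (k in seq_len(r)) {
    dk <- d[labels == pops[k], , drop = FALSE]
    nk <- colSums(!is.na(dk))
    nMat[k, ] <- nk
    pMat[k, ] <- ifelse(nk > 0, colMeans(dk, na.rm = TRUE) / 2, NA)
    hMat[k, ] <- ifelse(nk > 0, colSums(dk == 1, na.rm = TRUE) / nk, NA)
  }
  use <- colSums(nMat >= 1) == r & colSums(nMat) >= 2
  nbar <- colMeans(nMat)
  sumN <- colSums(nMat)
  nc <- (sumN - colSums(nMat^2) / sumN) / (r - 1)
  pbar <- colSums(nMat * pMat) / sumN
  s2 <- colSums(nMat * (pMat - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(nMat * hMat) / sumN

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  theta <- ifelse(tot != 0, a / tot, NA)
  a[!use] <- b[!use] <- cc[!use] <- NA; theta[!use] <- NA

  perSnp <- data.frame(chrom = mk$chrom, pos = mk$pos,
                       a = a, b = b, c = cc, fst = theta,
                       stringsAsFactors = FALSE)
  okA <- !is.na(a)
  overall <- sum(a[okA]) / sum(tot[okA])

  win <- lapply(split(seq_len(nrow(perSnp)), perSnp$chrom), function(idx) {
    w <- floor((perSnp$pos[idx] - 1) / windowBp)
    do.call(rbind, lapply(split(idx, w), function(ii) {
      ok <- ii[!is.na(a[ii])]
      wi <- floor((perSnp$pos[ii[1]] - 1) / windowBp)
      data.frame(chrom = perSnp$chrom[ii[1]],
                 windowStart = wi * windowBp + 1,
                 windowEnd = (wi + 1) * windowBp,
                 nSnps = length(ok),
                 fst = if (length(ok)) sum(a[ok]) / sum(tot[ok]) else NA,
                 stringsAsFactors = FALSE)
    }))
  })
  windowed <- do.call(rbind, win)
  rownames(windowed) <- NULL
  new("FstResult", perSnp = perSnp, windowed = windowed,
      overall = overall, windowBp = windowBp)
}

#' Greedy LD-based marker thinning
#'
#' Left-to-right scan within each chromosome: a SNP is dropped when its
#' squared Pearson correlation of dosages with any already-retained SNP
#' within `windowKb` upstream exceeds `r2Max`. Matches the greedy "thin"
#' behaviour of LD-pruning tools; ties keep the earlier-position SNP. Output
#' preserves the input marker order.
#'
#' @param geno a missing-free [GenotypeMatrix] with positions sorted within
#'   chromosome, or a plain dosage matrix plus `markers`.
#' @param r2Max squared-correlation cutoff (default 0.98).
#' @param windowKb physical window in kilobases (default 100).
#' @return integer vector of retained marker column indices.
#' @export
ldPrune <- function(geno, r2Max = 0.98, windowKb = 100) {
  d <- dosageMatrix(geno)
  mk <- markerInfo(geno)
  stopIfNot(!anyNA(d), "ldPrune requires a missing-free matrix")
  winBp <- windowKb * 1000
  n <- nrow(d)
  # pre-standardize columns so r = x'y / (n-1)
  mu <- colMeans(d)
  sd <- sqrt(pmax(colSums(d * d) - nrow(d) * mu^2, 0) / (nrow(d) - 1))
  keepAll <- integer(0)
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    stopIfNot(!is.unsorted(mk$pos[idx]), "positions must be sorted within chromosome")
    Z <- sweep(sweep(d[, idx, drop = FALSE], 2, mu[idx]), 2,
               pmax(sd[idx], .Machine$double.eps), "/")
    pos <- mk$pos[idx]
    retained <- integer(0)
    for (j in seq_along(idx)) {
      if (sd[idx[j]] == 0) next # constant column: carries no information
      inWin <- retained[pos[retained] >= pos[j] - winBp]
      drop <- FALSE
      if (length(inWin)) {
        r <- crossprod(Z[, inWin, drop = FALSE], Z[, j]) / (n - 1)
        if (any(r^2 > r2Max)) drop <- TRUE
      }
      if (!drop) retained <- c(retained, j)
    }
    keepAll <- c(keepAll, idx[retained])
  }
  sort(keepAll)
}
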