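#' Multi-environment mixed-model BLUP of genotype effects
#'
#' Fits, independently per trait, the two-way trial model
#' `y_ijk = mu + G_i + beta_j + alpha_k + (G x beta)_ij + e_ijk` with genotype
#' (`G_i`) and genotype-by-environment effects random and environment and
#' group effects fixed (with 4 environments and 2 groups, fixed treatment is
#' the identifiable choice). Variance components are estimated by REML via
#' \pkg{lme4}. Sum-to-zero contrasts are used so the intercept is the grand
#' mean; the corrected phenotype is `y_c = mu + BLUP(G_i)` (group effects are
#' not added back). When the data hold a single record per accession and
#' environment the interaction is inseparable from the residual and is
#' dropped (its variance is reported as `NA` and absorbed by `sigma2_E`).
#'
#' @param trials long-format data.frame with columns `accession`,
#'   `environment`, `group`, `trait`, `value`; at least two environments.
#' @return a [BlupResult].
#' @export
fitMultiEnvBlup <- function(trials) {
  need <- c("accession", "environment", "group", "trait", "value")
  stopIfNot(all(need %in% names(trials)),
            paste("trials must have columns", paste(need, collapse = ", ")))
  traits <- unique(trials$trait)
  fits <- lapply(traits, function(tr) {
    df <- trials[trials$trait == tr & !is.na(trials$value), , drop = FALSE]
    stopIfNot(length(unique(df$environment)) >= 2,
              "at least two environments are required")
    df$accession <- factor(df$accession)
    df$environment <- factor(df$environment)
    df$group <- factor(df$group)
    # each accession must belong to one group; a group carried by a single
    # accession is confounded with that accession's genotype effect
    gtab <- table(unique(df[, c("accession", "group")])$group)
    if (any(gtab < 2) && nlevels(df$group) > 1)
      stop("singular fixed-effect design: term 'group' is confounded with accession",
           call. = FALSE)
    hasGroups <- nlevels(df$group) > 1
    hasReps <- max(table(df$accession, df$environment)) > 1
    fixed <- if (hasGroups) "environment + group" else "environment"
    rand <- if (hasReps) "(1 | accession) + (1 | accession:environment)"
            else "(1 | accession)"
    form <- stats::as.formula(paste("value ~", fixed, "+", rand))
    contr <- list(environment = stats::contr.sum)
    if (hasGroups) contr$group <- stats::contr.sum
    fit <- lme4::lmer(form, data = df, REML = TRUE,
                      contrasts = contr,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
    fe <- lme4::fixef(fit)
    mu <- unname(fe["(Intercept)"])
    expandSum <- function(prefix, fac) {
      lev <- levels(fac)
      k <- length(lev)
      if (k == 1) return(stats::setNames(0, lev))
      eff <- fe[paste0(prefix, seq_len(k - 1))]
      stats::setNames(c(eff, -sum(eff)), lev)
    }
    envEff <- expandSum("environment", df$environment)
    grpEff <- if (hasGroups) expandSum("group", df$group)
              else stats::setNames(0, levels(df$group))
    re <- lme4::ranef(fit)$accession
    blups <- stats::setNames(re[, 1], rownames(re))
    vc <- as.data.frame(lme4::VarCorr(fit))
    varG <- vc$vcov[vc$grp == "accession"]
    varGxE <- if (hasReps) vc$vcov[vc$grp == "accession:environment"] else NA_real_
    varE <- vc$vcov[vc$grp == "Residual"]
    list(grandMean = mu, envEffects = envEff, groupEffects = grpEff,
         blups = blups, varG = varG, varGxE = varGxE, varE = varE,
         yc = mu + blups)
  })
  names(fits) <- traits
  new("BlupResult", fits = fits, traits = as.character(traits))
}

#' Per-trait descriptive statistics
#'
#' Mean, maximum, minimum, sample variance and coefficient of variation
#' (`cv = sd/mean`, as a fraction; `NA` when the mean is zero) of the raw
#' trial observations.
#'
#' @param trials long-format phenotype data.frame (see [fitMultiEnvBlup()]).
#' @return data.frame with one row per trait.
#' @export
descriptiveStats <- function(trials) {
  do.call(rbind, lapply(split(trials$value, trials$trait), function(v) {
    v <- v[!is.na(v)]
    stopIfNot(length(v) >= 2, "descriptiveStats needs at least two observations")
    m <- mean(v)
    data.frame(mean = m, max = max(v), min = min(v), variance = stats::var(v),
               cv = if (m == 0) NA_real_ else stats::sd(v) / m)
  })) -> out
  out$trait <- rownames(out)
  rownames(out) <- NULL
  out[, c("trait", "mean", "max", "min", "variance", "cv")]
}

#' REML SNP heritability on a thinned, frequency-weighted kinship
#'
#' Markers are thinned with [ldPrune()] (weights `w_j = 1` for retained SNPs,
#' 0 otherwise); the kinship is built from centred dosages with per-marker
#' scaling so that SNP `j` contributes proportionally to
#' `[2 p_j (1 - p_j)]^alphaPower` of the expected genetic variance (the
#' frequency-weighted baseline of LDAK-Thin-style heritability models, with
#' no annotation terms), normalised so its mean diagonal is ~1. The intercept
#' and the first `nPcs` principal components of that kinship are fitted as
#' fixed covariates, and the single-component restricted likelihood is
#' maximised over `delta = sigma2e/sigma2g` by a 1-D search on `log(delta)`
#' in `[-10, 10]` (tolerance 1e-6) after spectral decomposition.
#'
#' @param yc named numeric vector of corrected phenotypes, one per accession.
#' @param geno a missing-free [GenotypeMatrix] covering the same accessions.
#' @param alphaPower frequency exponent (default 0.75).
#' @param r2Max,windowKb thinning parameters (defaults 0.98 and 100).
#' @param nPcs number of PCs regressed out (default 4).
#' @return an [H2Estimate]; `boundary` is TRUE when the search ended at the
#'   edge of the delta range.
#' @export
estimateH2 <- function(yc, geno, alphaPower = 0.75, r2Max = 0.98,
                       windowKb = 100, nPcs = 4L) {
  d <- dosageMatrix(geno)
  stopIfNot(!anyNA(d), "estimateH2 requires a missing-free matrix")
  if (!is.null(names(yc))) {
    stopIfNot(all(rownames(d) %in% names(yc)), "yc must cover all accessions")
    yc <- yc[rownames(d)]
  }
  stopIfNot(length(yc) == nrow(d), "yc must hold one value per accession")

  keep <- ldPrune(geno, r2Max = r2Max, windowKb = windowKb)
  w <- numeric(ncol(d)); w[keep] <- 1
  dk <- d[, keep, drop = FALSE]
  p <- colMeans(dk) / 2
  hetv <- 2 * p * (1 - p)
  poly <- hetv > 0
  dk <- dk[, poly, drop = FALSE]; hetv <- hetv[poly]
  w[keep[!poly]] <- 0
  Wc <- sweep(dk, 2, colMeans(dk))
  Ws <- sweep(Wc, 2, hetv^((alphaPower - 1) / 2), "*")
  K <- tcrossprod(Ws) / sum(hetv^alphaPower)
  # unit mean diagonal so h2 is a variance proportion also for inbred panels
  # (the raw diagonal is ~1 + F_IS)
  K <- K / mean(diag(K))
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(eig$values, 1))
    stop("weighted kinship is not positive semidefinite within tolerance", call. = FALSE)
  nPcs <- min(nPcs, nrow(K) - 2L)
  X <- cbind(1, sweep(eig$vectors[, seq_len(nPcs), drop = FALSE], 2,
                      sqrt(pmax(eig$values[seq_len(nPcs)], 0)), "*"))
  fit <- remlSpectral(yc, X, eig)
  if (fit$boundary)
    warning("variance-ratio search ended at its boundary", call. = FALSE)
  new("H2Estimate", h2 = fit$h2, sigma2g = fit$sigmaG2, sigma2e = fit$sigmaE2,
      nSnpsUsed = ncol(dk), weights = w, alphaPower = alphaPower,
      boundary = fit$boundary)
}
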