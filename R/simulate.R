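#' Configuration for the structured genotype simulator
#'
#' The simulator follows the Balding-Nichols model: an ancestral allele
#' frequency is drawn uniformly on `[mafFloor, 1 - mafFloor]` for every SNP,
#' and each subpopulation's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` so that the expected fixation index among
#' subpopulations equals `fstTarget`. Diploid dosages are binomial draws from
#' the subpopulation frequency, except that with probability `ldRho` an
#' accession copies its own dosage at the previous SNP on the same chromosome,
#' which induces local LD without haplotype bookkeeping. The frequency process
#' is coupled to the same block structure: with probability `ldRho` a SNP also
#' reuses the previous SNP's subpopulation frequencies, the way neighbouring
#' SNPs on one haplotype block share their divergence. Without this coupling,
#' per-accession copying across independently diverged SNPs would average the
#' between-population signal away along a block and the realized Fst would
#' fall far below the target.
#'
#' @param nAccessions,nSnps,nChromosomes panel dimensions.
#' @param chromLengthBp chromosome length in bp (positions are drawn uniformly
#'   and kept strictly increasing within each chromosome).
#' @param nSubpops,subpopProportions subpopulation structure; proportions must
#'   sum to 1.
#' @param fstTarget divergence parameter `F` in `[0, 1)`; `F = 0` bypasses the
#'   Beta draw (all subpopulations share the ancestral frequency).
#' @param mafFloor minimum ancestral allele frequency.
#' @param ldRho per-adjacent-SNP copying probability in `[0, 1)`.
#' @param missingRate fraction of genotype calls masked as missing.
#' @param inbreeding within-individual fixation (F_IS) in `[0, 1]`: with this
#'   probability a call is drawn as a homozygote (`2 x Bernoulli(p)`), else as
#'   `Binomial(2, p)`. Selfing cereals are close to 1; the default 0 is the
#'   plain Balding-Nichols model. Allele frequencies, and hence the
#'   among-population Fst target, are unaffected.
#' @param seed RNG seed; the simulator is deterministic given the seed.
#' @return a `SimGenotypeConfig` object.
#' @export
simGenotypeConfig <- function(nAccessions, nSnps, nChromosomes = 1L,
                              chromLengthBp = 1e7, nSubpops = 2L,
                              subpopProportions = NULL, fstTarget = 0,
                              mafFloor = 0.05, ldRho = 0, missingRate = 0,
                              inbreeding = 0, seed = 1L) {
  if (is.null(subpopProportions))
    subpopProportions <- rep(1 / nSubpops, nSubpops)
  new("SimGenotypeConfig",
      nAccessions = as.integer(nAccessions), nSnps = as.integer(nSnps),
      nChromosomes = as.integer(nChromosomes), chromLengthBp = chromLengthBp,
      nSubpops = as.integer(nSubpops), subpopProportions = subpopProportions,
      fstTarget = fstTarget, mafFloor = mafFloor, ldRho = ldRho,
      missingRate = missingRate, inbreeding = inbreeding,
      seed = as.integer(seed))
}

#' @rdname simGenotypeConfig
#' @export
setClass("SimGenotypeConfig",
  slots = c(nAccessions = "integer", nSnps = "integer", nChromosomes = "integer",
            chromLengthBp = "numeric", nSubpops = "integer",
            subpopProportions = "numeric", fstTarget = "numeric",
            mafFloor = "numeric", ldRho = "numeric", missingRate = "numeric",
            inbreeding = "numeric", seed = "integer"))

setValidity("SimGenotypeConfig", function(object) {
  msg <- character(0)
  if (abs(sum(object@subpopProportions) - 1) > 1e-12)
    msg <- c(msg, "subpopProportions must sum to 1 within 1e-12")
  if (length(object@subpopProportions) != object@nSubpops)
    msg <- c(msg, "subpopProportions length must equal nSubpops")
  if (object@fstTarget < 0 || object@fstTarget >= 1)
    msg <- c(msg, "fstTarget must lie in [0, 1)")
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "ldRho must lie in [0, 1)")
  if (object@mafFloor < 0 || object@mafFloor >= 0.5)
    msg <- c(msg, "mafFloor must lie in [0, 0.5)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (object@inbreeding < 0 || object@inbreeding > 1)
    msg <- c(msg, "inbreeding must lie in [0, 1]")
  if (object@nSnps < object@nChromosomes)
    msg <- c(msg, "nSnps must be >= nChromosomes")
  if (object@nSnps > object@nChromosomes * object@chromLengthBp)
    msg <- c(msg, "more SNPs than available positions")
  if (length(msg)) msg else TRUE
})

#' Configuration for the multi-environment phenotype simulator
#'
#' Phenotypes follow the two-way trial model
#' `y_ijk = mu + G_i + beta_j + alpha_k + (G x beta)_ij + e_ijk` with additive
#' QTL genetic values. `h2Target` is the entry-mean (BLUP-scale) narrow-sense
#' heritability: `Var(g) / (Var(g) + (sigma2_gxe + sigma2_e)/nEnvironments)`,
#' i.e. the heritability of a phenotype averaged over environments, which is
#' the scale on which SNP heritability of BLUP values is estimated downstream.
#'
#' @param traits character vector of trait names.
#' @param nQtlPerTrait number of causal markers per trait.
#' @param h2Target entry-mean heritability in (0, 1]; scalar or one per trait.
#' @param nEnvironments number of environments (default 4).
#' @param envEffectSd spread of environment main effects, in units of the
#'   genetic standard deviation.
#' @param gxeVarFraction `sigma2_gxe / sigma2_g`, the fraction of genetic
#'   variance re-expressed as per-environment interaction deviations.
#' @param groupEffectSd spread of subpopulation main effects, in genetic-SD
#'   units.
#' @param cvTargets target coefficients of variation used to set trait means
#'   (recycled across traits); means are `sd(y) / cv`.
#' @param seed RNG seed.
#' @return a `SimPhenotypeConfig` object.
#' @export
simPhenotypeConfig <- function(traits, nQtlPerTrait, h2Target,
                               nEnvironments = 4L, envEffectSd = 1,
                               gxeVarFraction = 0.2, groupEffectSd = 0.5,
                               cvTargets = c(0.12, 0.2, 0.3, 0.45), seed = 1L) {
  new("SimPhenotypeConfig",
      traits = traits, nQtlPerTrait = as.integer(nQtlPerTrait),
      h2Target = rep_len(h2Target, length(traits)),
      nEnvironments = as.integer(nEnvironments), envEffectSd = envEffectSd,
      gxeVarFraction = gxeVarFraction, groupEffectSd = groupEffectSd,
      cvTargets = rep_len(cvTargets, length(traits)), seed = as.integer(seed))
}

#' @rdname simPhenotypeConfig
#' @export
setClass("SimPhenotypeConfig",
  slots = c(traits = "character", nQtlPerTrait = "integer", h2Target = "numeric",
            nEnvironments = "integer", envEffectSd = "numeric",
            gxeVarFraction = "numeric", groupEffectSd = "numeric",
            cvTargets = "numeric", seed = "integer"))

setValidity("SimPhenotypeConfig", function(object) {
  msg <- character(0)
  if (any(object@h2Target <= 0 | object@h2Target > 1))
    msg <- c(msg, "h2Target must lie in (0, 1]")
  if (object@gxeVarFraction < 0 || object@gxeVarFraction >= 1)
    msg <- c(msg, "gxeVarFraction must lie in [0, 1)")
  if (object@nEnvironments < 1) msg <- c(msg, "nEnvironments must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Simulate a structured genotype panel
#'
#' Balding-Nichols genotypes with optional local LD and missing calls; see
#' [simGenotypeConfig()] for the model. SNPs that come out monomorphic across
#' the whole panel are redrawn (up to 10 attempts) so that downstream kinship
#' computation is well defined.
#'
#' @param config a [simGenotypeConfig()] object.
#' @return list with `geno` (a [GenotypeMatrix]) and `labels` (named character
#'   vector of subpopulation labels per accession).
#' @export
simulateGenotypes <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    n <- config@nAccessions; m <- config@nSnps
    nChr <- config@nChromosomes
    perChr <- diff(round(seq(0, m, length.out = nChr + 1)))
    F <- config@fstTarget

    # subpopulation assignment
    counts <- floor(config@subpopProportions * n)
    rem <- n - sum(counts)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
    labels <- rep(paste0("pop", seq_len(config@nSubpops)), counts)
    ids <- sprintf("acc%03d", seq_len(n))
    names(labels) <- ids
    popIdx <- split(seq_len(n), labels)

    pAnc <- stats::runif(m, config@mafFloor, 1 - config@mafFloor)
    # subpopulation frequencies (Balding-Nichols); F = 0 shares pAnc
    pSub <- matrix(pAnc, nrow = config@nSubpops, ncol = m, byrow = TRUE)
    if (F > 0) {
      shape <- (1 - F) / F
      for (k in seq_len(config@nSubpops))
        pSub[k, ] <- stats::rbeta(m, pAnc * shape, (1 - pAnc) * shape)
    }

    fis <- config@inbreeding
    drawSnp <- function(j) {
      d <- numeric(n)
      for (k in seq_len(config@nSubpops)) {
        idx <- popIdx[[k]]
        nk <- length(idx)
        if (fis > 0) {
          hom <- stats::runif(nk) < fis
          d[idx] <- ifelse(hom, 2 * stats::rbinom(nk, 1, pSub[k, j]),
                           stats::rbinom(nk, 2, pSub[k, j]))
        } else {
          d[idx] <- stats::rbinom(nk, 2, pSub[k, j])
        }
      }
      d
    }

    dos <- matrix(0, n, m)
    chrom <- character(m); pos <- numeric(m)
    j0 <- 0
    for (ch in seq_len(nChr)) {
      mc <- perChr[ch]
      if (mc == 0) next
      pc <- sort(sample.int(config@chromLengthBp, mc))
      chrom[j0 + seq_len(mc)] <- paste0("chr", ch)
      pos[j0 + seq_len(mc)] <- pc
      for (jj in seq_len(mc)) {
        j <- j0 + jj
        sameBlock <- jj > 1 && config@ldRho > 0 &&
          stats::runif(1) < config@ldRho
        if (sameBlock) pSub[, j] <- pSub[, j - 1]
        d <- drawSnp(j)
        if (sameBlock) {
          copy <- stats::runif(n) < config@ldRho
          d[copy] <- dos[copy, j - 1]
        }
        # redraw panel-wide monomorphic SNPs (no copying on redraw); if the
        # subpopulation frequencies themselves are degenerate, redraw them too
        tries <- 0
        while (length(unique(d)) == 1 && tries < 10) {
          if (tries >= 3 && F > 0) {
            shape <- (1 - F) / F
            pSub[, j] <- stats::rbeta(config@nSubpops,
                                      pAnc[j] * shape, (1 - pAnc[j]) * shape)
          }
          d <- drawSnp(j)
          tries <- tries + 1
        }
        dos[, j] <- d
      }
      j0 <- j0 + mc
    }

    if (config@missingRate > 0) {
      nMiss <- round(config@missingRate * length(dos))
      dos[sample.int(length(dos), nMiss)] <- NA
    }
    rownames(dos) <- ids
    mk <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
    geno <- GenotypeMatrix(dos, mk,
      provenance = sprintf("simulated Balding-Nichols panel (F=%.3g, ldRho=%.2g, seed=%d)",
                           F, config@ldRho, config@seed))
    list(geno = geno, labels = labels)
  })
}

#' Simulate multi-environment phenotypes with known genetic truth
#'
#' Per trait: QTL markers are sampled, additive effects drawn `N(0, 1)`, and
#' the genetic value is the centred-dosage weighted sum. Environment, group,
#' genotype-by-environment and residual effects are added on the scale implied
#' by [simPhenotypeConfig()]; one record per accession and environment is
#' emitted.
#'
#' @param geno a [GenotypeMatrix] (missing calls are mean-filled internally
#'   for the genetic-value computation).
#' @param labels subpopulation labels per accession, as from
#'   [simulateGenotypes()].
#' @param config a [simPhenotypeConfig()] object.
#' @return list with `trials` (long-format data.frame: `accession`,
#'   `environment`, `group`, `trait`, `value`) and `truth` (per-trait QTL
#'   indices, effects, genetic values, realized entry-mean h2, plus the
#'   labels).
#' @export
simulatePhenotypes <- function(geno, labels, config) {
  validObject(config)
  d <- dosageMatrix(geno)
  if (anyNA(d)) { # mean fill for genetic values only
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  n <- nrow(d); m <- ncol(d); J <- config@nEnvironments
  ids <- rownames(d)
  stopIfNot(all(ids %in% names(labels)), "labels must cover all accessions")
  grp <- paste0("group", match(labels[ids], sort(unique(labels))))
  envs <- paste0("env", seq_len(J))

  withSeed(config@seed, {
    trials <- vector("list", length(config@traits))
    truth <- vector("list", length(config@traits))
    names(truth) <- config@traits
    Wc <- sweep(d, 2, colMeans(d))
    for (t in seq_along(config@traits)) {
      h2 <- config@h2Target[t]
      nq <- config@nQtlPerTrait
      stopIfNot(nq <= m, "nQtlPerTrait must be <= number of SNPs")
      if (h2 == 1 && config@gxeVarFraction > 0)
        stop("h2Target = 1 with gxeVarFraction > 0 is inconsistent", call. = FALSE)
      qtl <- sample.int(m, nq)
      eff <- stats::rnorm(nq)
      g <- drop(Wc[, qtl, drop = FALSE] %*% eff)
      names(g) <- ids
      sg2 <- stats::var(g)
      sdg <- sqrt(sg2)
      # entry-mean basis: h2 = sg2 / (sg2 + (s2gxe + s2e)/J)
      noisePerObs <- sg2 * (1 / h2 - 1) * J
      s2gxe <- config@gxeVarFraction * sg2
      s2e <- noisePerObs - s2gxe
      if (s2e < -1e-12)
        stop("gxeVarFraction too large for the requested h2Target", call. = FALSE)
      s2e <- max(s2e, 0)
      envEff <- stats::rnorm(J, 0, config@envEffectSd * sdg)
      groups <- sort(unique(grp))
      grpEff <- stats::rnorm(length(groups), 0, config@groupEffectSd * sdg)
      names(grpEff) <- groups
      gxe <- matrix(stats::rnorm(n * J, 0, sqrt(s2gxe)), n, J)
      err <- matrix(stats::rnorm(n * J, 0, sqrt(s2e)), n, J)
      dev <- g + sweep(gxe + err, 2, envEff, "+") + grpEff[grp]
      mu <- stats::sd(dev) / config@cvTargets[t]
      vals <- mu + dev
      trials[[t]] <- data.frame(
        accession = rep(ids, J), environment = rep(envs, each = n),
        group = rep(grp, J), trait = config@traits[t],
        value = as.vector(vals), stringsAsFactors = FALSE)
      realized <- sg2 / (sg2 + (stats::var(as.vector(gxe)) + stats::var(as.vector(err))) / J)
      if (s2gxe + s2e == 0) realized <- 1
      truth[[config@traits[t]]] <- list(qtl = qtl, effects = eff, g = g,
                                        realizedH2 = realized)
    }
    list(trials = do.call(rbind, trials),
         truth = list(perTrait = truth, labels = labels[ids]))
  })
}

#' Emulation preset: a 195-accession two-group panel
#'
#' Configuration pair mirroring the scale of a world oat germplasm panel:
#' 195 accessions in two subpopulations (75/120), 20,000 SNPs on 21
#' chromosomes, target Fst 0.24, seven agronomic traits measured in four
#' environments with entry-mean heritabilities spanning 0.55-0.76.
#'
#' @param seed RNG seed used for both configurations.
#' @param nSnps,nAccessions overrides for desk-scale runs.
#' @return list with `geno` and `pheno` configuration objects.
#' @export
presetOat195 <- function(seed = 1L, nSnps = 20000L, nAccessions = 195L) {
  list(
    geno = simGenotypeConfig(
      nAccessions = nAccessions, nSnps = nSnps, nChromosomes = 21L,
      chromLengthBp = 1e7, nSubpops = 2L,
      subpopProportions = c(75, 120) / 195, fstTarget = 0.24,
      mafFloor = 0.05, ldRho = 0.998, missingRate = 0.02, inbreeding = 0.95,
      seed = seed),
    pheno = simPhenotypeConfig(
      traits = c("PH", "CL", "FLL", "FLW", "SPP", "SD", "TN"),
      nQtlPerTrait = 50L,
      h2Target = seq(0.55, 0.76, length.out = 7),
      nEnvironments = 4L, envEffectSd = 1, gxeVarFraction = 0.2,
      groupEffectSd = 0.5, seed = childSeed(seed, 1L)))
}
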