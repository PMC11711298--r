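#' @import methods
NULL

#' GenotypeMatrix: accessions-by-SNP allele dosages with marker metadata
#'
#' Central genotype container. Rows are accessions, columns are biallelic SNP
#' markers; entries are alternate-allele dosages in `{0, 1, 2}`, `NA` for a
#' missing call, or real values in `[0, 2]` after mean imputation. Marker
#' metadata (chromosome, 1-based position, REF/ALT alleles) travels alongside,
#' and `provenance` accumulates a human-readable log of the filters applied.
#'
#' @slot dosages numeric matrix, accessions x markers; rownames are accession
#'   ids, colnames are marker ids.
#' @slot markers data.frame with columns `chrom`, `pos`, `ref`, `alt`, one row
#'   per marker, in column order of `dosages`.
#' @slot provenance character vector, one entry per processing step.
#'
#' @seealso [readVCF()], [filterSNPs()], [imputeMissing()], [simulateGenotypes()]
#' @export
setClass("GenotypeMatrix",
  slots = c(dosages = "matrix", markers = "data.frame", provenance = "character"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  mk <- object@markers
  msg <- character(0)
  if (!is.numeric(d)) msg <- c(msg, "dosages must be a numeric matrix")
  if (is.null(rownames(d))) msg <- c(msg, "dosages must have accession ids as rownames")
  else if (anyDuplicated(rownames(d))) msg <- c(msg, "accession ids must be unique")
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(mk)))
    msg <- c(msg, "markers must have columns chrom, pos, ref, alt")
  else {
    if (nrow(mk) != ncol(d)) msg <- c(msg, "markers rows must match dosage columns")
    if (nrow(mk) > 0) {
      if (any(mk$pos < 1)) msg <- c(msg, "marker positions must be >= 1")
      if (anyDuplicated(paste(mk$chrom, mk$pos)))
        msg <- c(msg, "(chrom, pos) pairs must be unique")
    }
  }
  v <- d[!is.na(d)]
  if (length(v) && (any(v < 0) || any(v > 2)))
    msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  if (length(msg)) msg else TRUE
})

#' KinshipMatrix: VanRaden genomic relationship matrix
#'
#' Accession-by-accession genomic relationship matrix `G = W W' / c` where `W`
#' holds allele-frequency-centred dosages and `c = 2 * sum(p_j (1 - p_j))` is
#' the VanRaden method-1 scaling constant.
#'
#' @slot values symmetric numeric matrix with accession ids as dimnames.
#' @slot scalingConstant the denominator `2 * sum(p_j (1 - p_j))`.
#' @slot alleleFreqs per-marker alternate-allele frequencies used for centring.
#'
#' @seealso [computeGRM()]
#' @export
setClass("KinshipMatrix",
  slots = c(values = "matrix", scalingConstant = "numeric", alleleFreqs = "numeric"))

setValidity("KinshipMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "kinship matrix must be square")
  else if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "kinship matrix must be symmetric within 1e-10")
  if (length(object@scalingConstant) != 1 || object@scalingConstant <= 0)
    msg <- c(msg, "scalingConstant must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' FstResult: Weir-Cockerham differentiation estimates
#'
#' Per-SNP variance components (`a` among populations, `b` among individuals
#' within populations, `c` within individuals) and theta = a/(a+b+c), window
#' estimates over non-overlapping genomic tiles, and the overall
#' ratio-of-sums estimate `sum(a) / sum(a+b+c)`.
#'
#' @slot perSnp data.frame: `chrom`, `pos`, `a`, `b`, `c`, `fst`.
#' @slot windowed data.frame: `chrom`, `windowStart`, `windowEnd`, `nSnps`, `fst`
#'   (1-based inclusive coordinates).
#' @slot overall single numeric, ratio-of-sums estimate across all SNPs.
#' @slot windowBp window width used.
#'
#' @seealso [weirCockerhamFst()]
#' @export
setClass("FstResult",
  slots = c(perSnp = "data.frame", windowed = "data.frame",
            overall = "numeric", windowBp = "numeric"))

#' BlupResult: multi-environment mixed-model BLUPs per trait
#'
#' Per-trait results of the two-way phenotype model
#' `y_ijk = mu + G_i + beta_j + alpha_k + (G x beta)_ij + e_ijk` with genotype
#' and genotype-by-environment effects random and environment and group
#' effects fixed. Corrected phenotypes are `y_c = mu + BLUP(G_i)`.
#'
#' @slot fits named list (one element per trait) with components `grandMean`,
#'   `envEffects`, `groupEffects`, `blups`, `varG`, `varGxE`, `varE`, `yc`.
#' @slot traits trait names.
#'
#' @seealso [fitMultiEnvBlup()], [correctedPhenotypes()]
#' @export
setClass("BlupResult", slots = c(fits = "list", traits = "character"))

#' H2Estimate: single-component REML SNP heritability
#'
#' @slot h2 heritability estimate `sigma2g / (sigma2g + sigma2e)`.
#' @slot sigma2g,sigma2e REML variance components.
#' @slot nSnpsUsed number of markers retained by LD thinning.
#' @slot weights per-marker 0/1 thinning weights.
#' @slot alphaPower frequency exponent of the weighted kinship.
#' @slot boundary TRUE if the variance-ratio search ended at a boundary.
#'
#' @seealso [estimateH2()]
#' @export
setClass("H2Estimate",
  slots = c(h2 = "numeric", sigma2g = "numeric", sigma2e = "numeric",
            nSnpsUsed = "integer", weights = "numeric", alphaPower = "numeric",
            boundary = "logical"))

setValidity("H2Estimate", function(object) {
  if (abs(object@h2 - object@sigma2g / (object@sigma2g + object@sigma2e)) > 1e-8)
    return("h2 must equal sigma2g / (sigma2g + sigma2e)")
  TRUE
})

#' GwasResult: mixed-linear-model association scan for one phenotype set
#'
#' @slot table data.frame with one row per tested SNP: `chrom`, `pos`, `beta`,
#'   `se`, `z`, `p`, `flag` (e.g. "constant" for monomorphic columns).
#' @slot trait trait label.
#' @slot phenoSet phenotype set label (an environment or "BLUP").
#' @slot nPcs number of principal components used as covariates.
#' @slot thresholds named numeric: Bonferroni p-value cutoffs at 5% and 1%.
#'
#' @seealso [mlmScan()], [rankMarkers()], [countTAS()]
#' @export
setClass("GwasResult",
  slots = c(table = "data.frame", trait = "character", phenoSet = "character",
            nPcs = "integer", thresholds = "numeric"))

setValidity("GwasResult", function(object) {
  p <- object@table$p
  if (length(p) && (any(p <= 0 | p > 1, na.rm = TRUE)))
    return("p-values must lie in (0, 1]")
  TRUE
})

#' GPModelSpec: family and hyperparameters of one prediction model
#'
#' @slot family one of "gblup", "ridge", "lasso", "elasticnet", "krr",
#'   "svr_linear", "svr_poly".
#' @slot hyper named list of family-specific hyperparameters.
#' @slot standardize whether features are centred and scaled inside `fitGP`
#'   (ignored by gblup, which centres by training allele frequencies).
#'
#' @seealso [gpModelSpec()], [fitGP()], [defaultGrid()]
#' @export
setClass("GPModelSpec",
  slots = c(family = "character", hyper = "list", standardize = "logical"))

#' GPModel: a fitted genomic prediction model
#'
#' Prediction is a pure function of the stored state and new genotypes.
#'
#' @slot spec the [GPModelSpec] used.
#' @slot state family-specific fitted state (coefficients or dual weights,
#'   centring/scaling constants, training features for kernel models).
#' @slot trainIds accession ids of the training rows.
#' @slot intercept fitted intercept.
#'
#' @seealso [fitGP()], [predictGP()]
#' @export
setClass("GPModel",
  slots = c(spec = "GPModelSpec", state = "list", trainIds = "character",
            intercept = "numeric"))

#' CVReport: repeated cross-validation benchmark results
#'
#' @slot cells data.frame with one row per (trait, model, repeat, fold):
#'   `accuracy`, `slope`, `mse`, `mae`, `hyper` (chosen hyperparameters,
#'   deparsed), `failed`.
#' @slot config list of the run configuration (folds, repeats, seed, models).
#'
#' @seealso [runCV()], [cvSummary()]
#' @export
setClass("CVReport", slots = c(cells = "data.frame", config = "list"))

#' SweepReport: GWAS-derived top-N marker-subset sweep results
#'
#' @slot cells data.frame as in [CVReport] plus `topN` ("all" for the
#'   all-marker baseline) and `mode` ("within_fold" or "whole_data").
#' @slot config run configuration.
#'
#' @seealso [markerSubsetSweep()]
#' @export
setClass("SweepReport", contains = "CVReport")
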