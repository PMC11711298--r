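#' Read a VCF into a GenotypeMatrix
#'
#' Parses a VCF (4.x, GT format field required) via \pkg{vcfR} and converts
#' diploid genotype calls to alternate-allele dosages: `0/0 -> 0`,
#' `0/1`/`1/0 -> 1`, `1/1 -> 2`; `./.` and `.|.` map to missing. Records with
#' more than one ALT allele are dropped (with a logged count) when
#' `biallelicOnly = TRUE`.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param biallelicOnly drop multiallelic records (default TRUE).
#' @return a [GenotypeMatrix].
#' @export
readVCF <- function(path, biallelicOnly = TRUE) {
  stopIfNot(file.exists(path), sprintf("VCF not found: %s", path))
  stopIfNot(file.size(path) > 0, sprintf("VCF is empty: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records", call. = FALSE)
  pos <- suppressWarnings(as.numeric(fix$POS))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop(sprintf("malformed VCF: non-numeric POS at data line %d", bad), call. = FALSE)
  }
  prov <- sprintf("read %d records from %s", nrow(fix), basename(path))
  keep <- rep(TRUE, nrow(fix))
  if (biallelicOnly) {
    multi <- grepl(",", fix$ALT, fixed = TRUE)
    if (any(multi)) {
      keep <- !multi
      prov <- c(prov, sprintf("dropped %d multiallelic record(s)", sum(multi)))
    }
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic records left after filtering", call. = FALSE)

  alleleCount <- function(x) {
    # count of "1" alleles; NA if any allele missing
    x <- gsub("|", "/", x, fixed = TRUE)
    parts <- strsplit(x, "/", fixed = TRUE)
    vapply(parts, function(a) {
      if (any(a == "." ) || any(is.na(a))) return(NA_real_)
      a <- suppressWarnings(as.numeric(a))
      if (anyNA(a) || any(a > 1)) return(NA_real_)
      sum(a)
    }, numeric(1))
  }
  # fast path: map the handful of common GT strings
  lut <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
           "1/1" = 2, "1|1" = 2, "./." = NA, ".|." = NA, "." = NA)
  d <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
              dimnames = list(colnames(gt), rownames(gt)))
  for (j in seq_len(nrow(gt))) {
    row <- gt[j, ]
    known <- row %in% names(lut) | is.na(row)
    v <- unname(lut[row])
    if (!all(known)) v[!known] <- alleleCount(row[!known])
    d[, j] <- v
  }
  mk <- data.frame(chrom = fix$CHROM, pos = pos[keep],
                   ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  GenotypeMatrix(d, mk, provenance = prov)
}

#' Write a simulated panel to a VCF and phenotype CSV fixture
#'
#' Writes a minimal standards-compliant VCF 4.2 (GT-only FORMAT, `./.` for
#' missing calls) and a long-format phenotype CSV with header
#' `accession,environment,group,trait,value`. Dosages must be integral
#' (0/1/2): fixtures represent raw calls, not imputed values. The pair
#' round-trips losslessly through [readVCF()].
#'
#' @param geno a [GenotypeMatrix] with integral dosages.
#' @param trials long-format phenotype data.frame (or NULL to skip).
#' @param dir output directory (created if needed).
#' @param overwrite refuse to clobber existing files unless TRUE.
#' @return invisibly, the paths written.
#' @export
writeFixture <- function(geno, trials, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcfPath <- file.path(dir, "genotypes.vcf")
  csvPath <- file.path(dir, "phenotypes.csv")
  if (!overwrite && (file.exists(vcfPath) || (!is.null(trials) && file.exists(csvPath))))
    stop("fixture files exist; use overwrite = TRUE to replace them", call. = FALSE)

  d <- dosageMatrix(geno)
  ok <- is.na(d) | d %in% c(0, 1, 2)
  stopIfNot(all(ok), "writeFixture requires integral dosages in {0, 1, 2}")
  mk <- markerInfo(geno)
  gtCode <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=gwasGP.writeFixture",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  lines <- vapply(seq_len(ncol(d)), function(j) {
    gt <- ifelse(is.na(d[, j]), "./.", gtCode[d[, j] + 1])
    paste(c(mk$chrom[j], mk$pos[j], colnames(d)[j], mk$ref[j], mk$alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), vcfPath)
  if (!is.null(trials))
    utils::write.csv(trials, csvPath, row.names = FALSE, quote = FALSE)
  invisible(c(vcf = vcfPath, csv = if (!is.null(trials)) csvPath))
}

#' Marker quality-control filters
#'
#' Keeps SNP `j` iff `MAF_j > mafMin` AND heterozygote fraction `< hetMax` AND
#' missing fraction `< missingMax` (strict inequalities). MAF and
#' heterozygosity are computed over non-missing calls; the missing fraction
#' over all calls. Heterozygosity is the fraction of dosage-1 calls. The
#' filter log records the count removed by each rule (a SNP failing several
#' rules is attributed to the first in the order above).
#'
#' @param geno a [GenotypeMatrix].
#' @param mafMin minor-allele-frequency cutoff (default 0.01).
#' @param hetMax heterozygosity cutoff (default 0.20).
#' @param missingMax missing-fraction cutoff (default 0.70).
#' @return the filtered [GenotypeMatrix]; errors if nothing survives.
#' @export
filterSNPs <- function(geno, mafMin = 0.01, hetMax = 0.20, missingMax = 0.70) {
  for (v in c(mafMin, hetMax, missingMax))
    stopIfNot(v >= 0 && v <= 1, "filter thresholds must lie in [0, 1]")
  d <- dosageMatrix(geno)
  nObs <- colSums(!is.na(d))
  p <- alleleFreqs(d)
  maf <- pmin(p, 1 - p)
  het <- colSums(d == 1, na.rm = TRUE) / pmax(nObs, 1)
  missFrac <- 1 - nObs / nrow(d)

  failMaf <- !(maf > mafMin) | nObs == 0
  failHet <- !failMaf & !(het < hetMax)
  failMiss <- !failMaf & !failHet & !(missFrac < missingMax)
  keep <- !(failMaf | failHet | failMiss)
  if (!any(keep))
    stop("all SNPs removed by QC filters; relax the thresholds", call. = FALSE)
  log <- sprintf("QC: removed %d by MAF<=%.3g, %d by het>=%.3g, %d by missing>=%.3g; kept %d/%d",
                 sum(failMaf), mafMin, sum(failHet), hetMax,
                 sum(failMiss), missingMax, sum(keep), ncol(d))
  GenotypeMatrix(d[, keep, drop = FALSE], markerInfo(geno)[keep, , drop = FALSE],
                 provenance = c(provenance(geno), log))
}

#' Mean-impute missing dosages
#'
#' Replaces every missing call by the SNP's mean non-missing dosage (a real
#' value in `[0, 2]`), the standard self-contained fallback for genomic
#' prediction. Haplotype-based imputation is out of scope; pre-imputed VCFs
#' pass through unchanged.
#'
#' @param geno a [GenotypeMatrix] (post-QC).
#' @return a complete (missing-free) [GenotypeMatrix].
#' @export
imputeMissing <- function(geno) {
  d <- dosageMatrix(geno)
  if (!anyNA(d)) return(geno)
  nObs <- colSums(!is.na(d))
  if (any(nObs == 0))
    stop("SNP(s) with zero non-missing calls; run filterSNPs first", call. = FALSE)
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  nFilled <- nrow(idx)
  d[idx] <- mu[idx[, 2]]
  GenotypeMatrix(d, markerInfo(geno),
                 provenance = c(provenance(geno),
                                sprintf("mean-imputed %d missing call(s)", nFilled)))
}
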