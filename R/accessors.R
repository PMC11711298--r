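#' @rdname GenotypeMatrix-class
#' @param dosages accessions x markers numeric matrix (rownames = accession ids).
#' @param markers data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param provenance character log.
#' @export
GenotypeMatrix <- function(dosages, markers, provenance = character(0)) {
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0(markers$chrom, "_", markers$pos)
  rownames(markers) <- NULL
  new("GenotypeMatrix", dosages = dosages,
      markers = as.data.frame(markers), provenance = provenance)
}

#' Accessors for GenotypeMatrix
#'
#' @param x a [GenotypeMatrix].
#' @return `dosageMatrix` the numeric dosage matrix; `markerInfo` the marker
#'   metadata data.frame; `accessionIds` the accession id vector;
#'   `nAccessions`/`nMarkers` dimensions; `provenance` the filter log.
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
dosageMatrix <- function(x) x@dosages

#' @rdname genotype-accessors
#' @export
markerInfo <- function(x) x@markers

#' @rdname genotype-accessors
#' @export
accessionIds <- function(x) rownames(x@dosages)

#' @rdname genotype-accessors
#' @export
nAccessions <- function(x) nrow(x@dosages)

#' @rdname genotype-accessors
#' @export
nMarkers <- function(x) ncol(x@dosages)

#' @rdname genotype-accessors
#' @export
provenance <- function(x) x@provenance

setMethod("show", "GenotypeMatrix", function(object) {
  d <- object@dosages
  miss <- mean(is.na(d))
  cat("GenotypeMatrix:", nrow(d), "accessions x", ncol(d), "markers\n")
  cat(sprintf("  missing calls: %.2f%%; chromosomes: %d\n",
              100 * miss, length(unique(object@markers$chrom))))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " | "), "\n")
})

#' @rdname KinshipMatrix-class
#' @param x a [KinshipMatrix].
#' @export
kinshipValues <- function(x) x@values

#' @rdname KinshipMatrix-class
#' @export
scalingConstant <- function(x) x@scalingConstant

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix:", nrow(object@values), "accessions; mean diagonal",
      sprintf("%.3f", mean(diag(object@values))),
      "; scaling constant", sprintf("%.3f", object@scalingConstant), "\n")
})

setMethod("show", "FstResult", function(object) {
  cat("FstResult:", nrow(object@perSnp), "SNPs,", nrow(object@windowed),
      sprintf("windows of %d bp; overall theta = %.4f\n",
              as.integer(object@windowBp), object@overall))
})

#' @rdname FstResult-class
#' @param x an [FstResult].
#' @export
overallFst <- function(x) x@overall

#' @rdname FstResult-class
#' @export
perSnpFst <- function(x) x@perSnp

#' @rdname FstResult-class
#' @export
windowedFst <- function(x) x@windowed

#' Corrected phenotypes from a multi-environment BLUP fit
#'
#' @param x a [BlupResult].
#' @return numeric matrix accessions x traits of `y_c = mu + BLUP(G_i)`.
#' @export
correctedPhenotypes <- function(x) {
  ids <- sort(unique(unlist(lapply(x@fits, function(f) names(f$yc)))))
  out <- sapply(x@fits, function(f) f$yc[ids])
  rownames(out) <- ids
  out
}

#' @rdname BlupResult-class
#' @param x a [BlupResult].
#' @export
varianceComponents <- function(x) {
  do.call(rbind, lapply(names(x@fits), function(tr) {
    f <- x@fits[[tr]]
    data.frame(trait = tr, varG = f$varG, varGxE = f$varGxE, varE = f$varE)
  }))
}

setMethod("show", "BlupResult", function(object) {
  cat("BlupResult:", length(object@traits), "trait(s):",
      paste(object@traits, collapse = ", "), "\n")
  print(varianceComponents(object), row.names = FALSE)
})

setMethod("show", "H2Estimate", function(object) {
  cat(sprintf("H2Estimate: h2 = %.3f (sigma2g = %.3g, sigma2e = %.3g), %d SNPs%s\n",
              object@h2, object@sigma2g, object@sigma2e, object@nSnpsUsed,
              if (object@boundary) " [boundary]" else ""))
})

setMethod("show", "GwasResult", function(object) {
  cat("GwasResult:", object@trait, "/", object@phenoSet, "-",
      nrow(object@table), "SNPs;",
      sum(object@table$p < object@thresholds["5%"], na.rm = TRUE),
      "below the 5% Bonferroni threshold\n")
})

#' @rdname GwasResult-class
#' @param x a [GwasResult].
#' @export
gwasTable <- function(x) x@table

#' @rdname GwasResult-class
#' @export
gwasThresholds <- function(x) x@thresholds

setMethod("show", "GPModelSpec", function(object) {
  h <- if (length(object@hyper))
    paste(names(object@hyper), unlist(object@hyper), sep = "=", collapse = ", ")
  else "(defaults)"
  cat("GPModelSpec:", object@family, "-", h, "\n")
})

setMethod("show", "GPModel", function(object) {
  cat("Fitted GPModel:", object@spec@family, "on",
      length(object@trainIds), "accessions\n")
})

setMethod("show", "CVReport", function(object) {
  cat(class(object), "-", nrow(object@cells), "cells\n")
  print(cvSummary(object), row.names = FALSE)
})

#' @rdname CVReport-class
#' @param x a [CVReport] or [SweepReport].
#' @export
cvCells <- function(x) x@cells
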