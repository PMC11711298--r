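# shared simulated fixtures, built once per test run and cached

.panelCache <- new.env(parent = emptyenv())

cachedPanel <- function(key, builder) {
  if (is.null(.panelCache[[key]])) .panelCache[[key]] <- builder()
  .panelCache[[key]]
}

# a small structured, inbred panel used across popgen/gwas/gp tests
structuredPanel <- function() {
  cachedPanel("structured", function() {
    cfg <- simGenotypeConfig(150, 2000, nChromosomes = 4, fstTarget = 0.24,
                             ldRho = 0.3, inbreeding = 0.9, seed = 301)
    simulateGenotypes(cfg)
  })
}

# hand-held toy: 3 accessions x 2 SNPs, dosages ((0,2),(1,1),(2,0))
toyGeno <- function() {
  d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
              dimnames = list(c("a1", "a2", "a3"), c("s1", "s2")))
  GenotypeMatrix(d, data.frame(chrom = c("chr1", "chr1"), pos = c(100, 200),
                               ref = "A", alt = "C"))
}

# wrap a plain dosage matrix as a GenotypeMatrix with evenly spaced positions
asGeno <- function(d, chrom = "chr1", spacing = 1000) {
  if (is.null(rownames(d))) rownames(d) <- sprintf("acc%03d", seq_len(nrow(d)))
  GenotypeMatrix(d, data.frame(chrom = chrom, pos = seq_len(ncol(d)) * spacing,
                               ref = "A", alt = "C"))
}

# named phenotype vector aligned to a genotype object
namedPheno <- function(geno, values) stats::setNames(values, accessionIds(geno))
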