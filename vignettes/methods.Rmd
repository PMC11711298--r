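---
title: "Methods: GWAS-informed genomic prediction benchmarking with gwasGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GWAS-informed genomic prediction benchmarking with gwasGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gwasGP` benchmarks genomic prediction (GP) of quantitative agronomic traits
in structured germplasm panels, with and without GWAS-informed marker
selection. The pipeline starts from a biallelic SNP dosage matrix (read from
VCF) and a long-format multi-environment phenotype table and runs through
marker QC, mixed-model BLUP of genotype effects, population-genetic
summaries, REML SNP heritability, a mixed-linear-model association scan, and
a repeated cross-validation comparison of seven prediction model families.
A synthetic-data module generates panels with known genetic truth so that
every stage is testable at desk scale without external data.

# The phenotype model and corrected phenotypes

Trials are modelled per trait as

$$ y_{ijk} = \mu + G_i + \beta_j + \alpha_k + (G\times\beta)_{ij} + e_{ijk} $$

with genotype ($G_i$) and genotype-by-environment effects random and
environment ($\beta_j$) and group ($\alpha_k$) effects fixed. Environment and
group are treated as fixed even though all terms could formally be declared
random: with a handful of environments and two subpopulation groups, fixed
treatment is the identifiable choice and leaves the random part to the two
terms for which shrinkage is meaningful. Variance components are estimated by
REML via `lme4::lmer` with sum-to-zero contrasts, so the intercept estimates
the grand mean. The corrected phenotype carried downstream is
$y_c = \hat\mu + \mathrm{BLUP}(G_i)$; group effects are *not* added back, so
$y_c$ measures genotype merit net of subpopulation mean differences that are
modelled as fixed. When the data hold exactly one record per accession and
environment, the interaction is inseparable from the residual; the fitted
model then drops the interaction term and reports its variance as `NA`
(absorbed by $\sigma^2_E$).

A consequence worth knowing: in a structured panel part of the *genetic*
variance lies between groups. Because the group term is fixed, that
between-group genetic component is excluded from $y_c$, and a noise-free
simulation recovers the genetic values with $r = 1$ only on an unstructured
panel. This is by design, not an estimation error.

# Marker QC and imputation

SNPs are kept iff MAF > 1%, heterozygote fraction < 20% and missing fraction
< 70%, all strict inequalities, with MAF and heterozygosity computed on
observed calls and the missing fraction over all calls. Missing calls are
then replaced by the per-SNP mean dosage. Haplotype-based imputation is a
deliberate non-goal: mean fill is the standard self-contained fallback for
genomic prediction, and users who prefer haplotype imputation can feed a
pre-imputed VCF through the same reader.

# Population genetics

* **Kinship** is VanRaden method 1, $G = WW'/(2\sum_j p_j(1-p_j))$, with $W$
  centred by twice the allele frequency of the analysed panel itself.
* **PCA** is the eigendecomposition of that kinship; explained-variance
  fractions are eigenvalues over the trace.
* **Fst** is the Weir & Cockerham (1984) variance-components estimator with
  the random-union-of-gametes heterozygosity correction, reported per SNP,
  in non-overlapping 30-kb tiles, and overall. Window and overall estimates
  are always ratio-of-sums, never means of per-SNP ratios. Non-overlapping
  tiling was chosen because the common windowed-Fst tooling defaults to it
  when no step is given.
* **LD thinning** is a greedy left-to-right scan per chromosome dropping any
  SNP whose $r^2$ with an already retained SNP within 100 kb upstream
  exceeds 0.98; ties keep the earlier position.

# SNP heritability

`estimateH2` implements a single-component REML on a thinned,
frequency-weighted kinship: thinned markers get weight 1 (others 0), and
marker $j$ contributes to the kinship in proportion to
$[2p_j(1-p_j)]^{0.75}$, the baseline frequency weighting of
expectation-based heritability models. Annotation-dependent terms are out of
scope and deliberately dropped: no functional annotations exist in this
pipeline, so only the baseline term is implemented. The kinship is
normalised to unit mean diagonal so that $h^2 = \sigma^2_g/(\sigma^2_g +
\sigma^2_e)$ reads as a variance proportion also for inbred panels, whose
raw diagonal is inflated by $1 + F_{IS}$. The intercept and the first four
principal components are fixed covariates; the restricted likelihood is
profiled over $\delta = \sigma^2_e/\sigma^2_g$ by a one-dimensional search
on $\log\delta \in [-10, 10]$ (tolerance $10^{-6}$) after a spectral
decomposition, and a boundary flag is raised when the search ends at either
edge. At a few hundred accessions the sampling error of a single estimate is
substantial (standard error roughly $\sqrt{2\,M_e}/n$ with $M_e$ the
effective marker dimension), which is why recovery checks average over many
simulated panels.

# Association scan

`mlmScan` is a P3D/EMMAX-style scan: $\delta$ is estimated once under the
null model (intercept + 3 kinship PCs + polygenic term), the implied
whitening is applied to phenotype, covariates and markers, and each marker
is tested by generalized least squares with a two-sided Wald normal test.
The phenotype is standardized internally (effects are reported back on the
input scale), which makes p-values exactly invariant to affine transforms
of $y_c$, and the null-model search tolerance is tightened to $10^{-10}$ so
that the P3D weights are reproducible at that level. `delta = Inf` disables
the polygenic term and reduces the scan to ordinary least squares — useful
for testing and for unstructured panels. Multi-model scan suites (the
iterative multi-locus algorithms of the common GWAS toolboxes) are not
reimplemented; the scan here is the in-package ranking engine, and
externally computed p-value tables can be supplied to the ranking and
counting functions instead. Rankings across phenotype sets (environments
plus BLUP) take the per-SNP minimum p-value, with ties broken by
chromosome and position.

# Prediction models

All seven families sit behind one `fitGP`/`predictGP` contract:

* **gblup** — intercept-only mixed model with $u \sim N(0, G\sigma^2_u)$;
  the variance ratio is REML-estimated on the training fold (or fixed). The
  grand mean is estimated by the training sample mean rather than
  generalized least squares; the two differ by $O(1/n)$ and the sample-mean
  convention is what makes GBLUP and ridge regression on centred dosages
  *numerically identical* (the RR-BLUP equivalence), which the test suite
  asserts at $10^{-8}$.
* **ridge** — closed form via the dual system; penalty $\lambda\|\beta\|^2/2$
  on $\tfrac12\mathrm{RSS}$.
* **lasso / elastic net** — cyclic coordinate descent with soft
  thresholding on
  $\tfrac12\mathrm{RSS} + \lambda(\alpha\|\beta\|_1 + \tfrac{1-\alpha}2\|\beta\|_2^2)$,
  warm-started along a geometric path, with an active-set strategy whose
  KKT screen does not mutate coefficients (important under strong local LD,
  where exactly collinear marker groups would otherwise shuffle membership
  between passes and stall convergence). Convergence is a maximum
  coefficient change below `tol` (default $10^{-7}$, at most 10,000 sweeps,
  loud failure otherwise). The generalized bridge penalty for arbitrary
  exponents is *not* fitted — no algorithm exists for the general case in
  scope — only its named special cases (lasso, ridge, their mixture).
* **krr** — kernel ridge regression in the dual, with linear, polynomial
  $(\gamma\langle x,y\rangle + r)^d$ (the default) and RBF kernels.
* **svr_linear / svr_poly** — $\varepsilon$-insensitive support vector
  regression solved in the dual by `kernlab::ksvm` on precomputed kernel
  matrices of the standardized features. The loss is the standard two-sided
  $\varepsilon$-insensitive loss.

Features are centred always (so the intercept decouples exactly) and scaled
to unit variance by default; phenotype centring happens inside the fit. A
single absolute penalty grid is only meaningful on standardized features,
which is why standardization is the default. GBLUP ignores the flag and
centres raw dosages by training allele frequencies.

Tuning uses grid search with internal k-fold cross-validation on the
training fold only, selecting by mean internal accuracy with ties going to
the smaller penalty / simpler kernel. `defaultGrid()` carries the documented
full grids (13 log-spaced $\lambda$, five mixing values, and so on);
`deskGrid()` carries reduced grids whose penalty weights are expressed
relative to a per-fold scale (top Gram eigenvalue for ridge/KRR,
$\lambda_{\max}$ for the L1 families), which keeps a small grid meaningful
across traits and fold sizes. Engine-internal tuning fits use
phenotype-scaled convergence tolerances and a sweep cap: a tuning iterate
that is accurate to a small fraction of the phenotype SD selects
hyperparameters exactly as well as a fully converged one, at a fraction of
the cost. User-facing `fitGP` always honours its strict documented
tolerance.

# Cross-validation benchmark

`runCV` repeats a 5-fold split (random near-equal parts, 80%/20%
train/test), tunes every family per fold as above, refits on the full
training fold and scores the held-out fold with four metrics: Pearson
accuracy, unbiasedness slope ($\mathrm{cov}(y_c,y_p)/\mathrm{var}(y_p)$,
observed regressed on predicted), MSE and MAE over the test individuals.
Per-fold metrics are averaged over folds and repeats (per-fold averaging
rather than pooled predictions). All randomness derives from one seed
through a hierarchical scheme (repeat index → fold seed; fold index →
tuning seed), so adding a model or a trait never changes the splits, and a
sweep's all-marker baseline is bit-identical to the plain `runCV` baseline
under the same seed. A family that fails on a fold is recorded as a failed
cell and the run continues.

`markerSubsetSweep` evaluates top-N GWAS-ranked marker subsets against the
all-marker baseline under identical folds. Two ranking modes exist because
published analyses are often ambiguous about where the ranking was
computed: `within_fold` (default) recomputes the scan and ranking on each
training fold only and is leakage-safe; `whole_data` ranks once on all
accessions and is optimistically biased — the report flags it, and the test
suite demonstrates the bias direction on a null trait. The model family
evaluated across a sweep is held fixed (intended: the best family from the
all-marker comparison).

# The synthetic-data generator

Genotypes follow the Balding–Nichols model: ancestral frequencies uniform
on $[\mathrm{mafFloor}, 1-\mathrm{mafFloor}]$, subpopulation frequencies
Beta-distributed around them with divergence parameter $F$, diploid dosages
binomial. Three extensions make the panels behave like real selfing-crop
germplasm:

* **Inbreeding** (`inbreeding`, $F_{IS}$): with this probability a call is
  drawn as a homozygote. Selfing cereals sit near 1; without this, HWE
  heterozygosity (~$2pq$) would collide with the 20% heterozygosity QC cut
  that such panels are routinely filtered with.
* **Local LD** (`ldRho`): an accession copies its own dosage at the
  previous SNP with probability `ldRho`. The subpopulation frequency
  process is coupled to the same block structure — with probability `ldRho`
  a SNP reuses the previous SNP's subpopulation frequencies, the way
  neighbouring SNPs on one haplotype block share their divergence. Without
  that coupling, copying across independently diverged SNPs averages the
  between-population signal away along a block and the realized Fst
  collapses far below its target (we measured this directly during
  development). With it, realized panel-wide Fst matches the Beta-model
  target.
* **Monomorphic resampling**: panel-wide monomorphic SNPs are redrawn (the
  subpopulation frequencies too, if they were degenerate), so kinship
  computation is always well defined at the default MAF floor.

Phenotypes: per trait, QTL markers are sampled uniformly, effects are
standard normal, and the genetic value is the centred-dosage weighted sum.
`h2Target` is defined on the **entry-mean basis**:
$\mathrm{Var}(g) / (\mathrm{Var}(g) + (\sigma^2_{g\times e} +
\sigma^2_e)/n_\mathrm{env})$ — the heritability of a phenotype averaged
over environments, which is the scale on which SNP heritability of BLUP
values is estimated. (Under the per-observation reading, a BLUP across four
environments would mechanically recover a much higher value than the
target, making "recovery" meaningless.) $\sigma^2_{g\times e}$ is a
configured fraction of the genetic variance; environment and group main
effects scale with the genetic SD. Trait means are set from target
coefficients of variation, so descriptive statistics land in the realistic
agronomic range (roughly 10–50%).

**The emulation preset** (`presetOat195()`) mirrors a world oat germplasm
panel: 195 accessions in two groups (75/120), 20,000 SNPs on 21
chromosomes of $10^7$ bp, target Fst 0.24, $F_{IS} = 0.95$, 2% missing
calls, seven traits in four environments with entry-mean heritabilities
0.55–0.76, 50 QTL per trait and a G×E fraction of 0.2. `ldRho = 0.998`
was calibrated so that the panel's *effective marker dimension* (on the
order of a hundred independent haplotype blocks) reproduces the all-marker
prediction accuracies reported for real oat panels of this size (roughly
0.4–0.7 across model families): candidate values of `ldRho` were screened
once against that target and the best match frozen. With weak LD the same
marker count would give an effective dimension of tens of thousands and no
model could exceed ~0.15 accuracy at $n = 195$ — a regime real GBS panels
of inbred lines are demonstrably not in. This is a one-time scientific
calibration of the generator to its emulation target, not a tunable of the
analysis methods.

What the generator does *not* emulate: coalescent recombination structure,
allele-frequency spectra from demography, family/pedigree substructure
within groups, dominance and epistasis, selection, and environment-specific
variance heterogeneity. Passing tests therefore demonstrate internal
correctness and realistic qualitative behaviour, not performance claims
about any real panel.

# Numerical choices and degenerate inputs

* REML searches run on $\log\delta \in [-10, 10]$; estimates at a boundary
  carry a flag (heritability) or simply mean "no signal" (GBLUP tuning).
* Constant marker columns: p-value 1 with a `"constant"` flag in scans;
  zero-variance features are centred but not scaled in standardization;
  constant columns carry no information in LD pruning and are skipped.
* Fold-internal monomorphic markers contribute zero to both the numerator
  and the scaling constant of fold-level kinships (the strict
  `computeGRM` contract still refuses monomorphic columns for user-facing
  calls).
* Exact score ties in tuning resolve to the smaller penalty; grid rows are
  canonically ordered so the resolution is deterministic.
* `gpMetrics` reports accuracy and slope as `NA` when predictions are
  constant; MSE/MAE are always defined.
* The problem sizes used by the automated checks (panels of 195–400
  accessions, 4,000–20,000 markers, 5–20 repeats) were chosen as the
  smallest sizes at which the statistical claims are stable; the full-scale
  settings (500 repeats, full grids) are a flag away.

# Known limitations

* The association scan is a single P3D mixed-model scan; multi-locus
  iterative methods typically find more associations on real data.
* Mean imputation attenuates marker effects at high missingness compared to
  haplotype imputation.
* The entry-mean heritability definition ties `h2Target` to the number of
  environments; comparing panels simulated with different `nEnvironments`
  at equal `h2Target` implies different per-plot noise.
* Balding–Nichols panels have no within-group relatedness gradient, so
  prediction accuracy leans more on block-level LD than a real pedigreed
  panel would.
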