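---
title: "Methods: candidate-gene SNP-SNP interaction scans with a permutation min-p null"
author: "episnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene SNP-SNP interaction scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episnp)
```

This vignette documents the statistical model, the procedure, the tunable
parameters, and the design decisions behind `episnp`. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The model and the test

For one index-gene SNP $A$ and one partner-gene SNP $B$, with allelic
dosages $d_A, d_B \in [0, 2]$ counting copies of the dataset-minor allele,
the case-control outcome $y$ is modelled by logistic regression

$$\operatorname{logit} P(y = 1) = \beta_0 + \beta_1 d_A + \beta_2 d_B +
\beta_3\, d_A d_B + \gamma' c,$$

where $c$ collects the adjustment covariates: reference-coded study-site
indicators and the first $k$ (default 2) ancestry principal components.
Statistical epistasis is a nonzero $\beta_3$: a departure of the joint
log-odds from additivity of the two margins. The test statistic is the Wald
$z = \hat\beta_3 / \widehat{se}(\hat\beta_3)$ referred to a standard normal,
two-sided ($z^2$ is the equivalent $\chi^2_1$ form). Dosages enter
untransformed (additive allelic coding); fractional values from imputation
are used as-is.

Fitting is by Newton/IRLS with step-halving, implemented in compiled code
because the permutation null refits the model millions of times.
Convergence requires a maximum absolute score below $10^{-8}$ or a relative
log-likelihood change below $10^{-10}$, within 50 iterations; standard
errors come from the inverse observed information at the optimum. Two
degenerate outcomes are recognised and excluded from downstream minima
rather than silently assigned a p-value:

* **COLLINEAR** — the design is numerically rank-deficient (Cholesky pivot
  below $10^{-8}$ of scale). This happens, deliberately, when the same SNP
  or two perfectly correlated SNPs appear on both sides of a pair: the
  interaction coefficient is undefined there, and returning a p-value would
  bias the gene-level minimum.
* **NON_CONVERGED** — no convergence within 50 iterations, or any
  coefficient escaping $\pm 15$ on the dosage scale, the usual symptom of
  complete or quasi-complete separation (at $|\beta| = 15$ a single allele
  copy shifts the odds by $e^{15}$, far beyond anything estimable in this
  design, so the bound only triggers on genuinely divergent fits).

Missing dosages are dropped pairwise-complete per test. Whether the original
analyses retained non-converged pairs is not documentable; exclusion plus
itemised reporting is the package's choice, and the per-scan skip count
makes the decision visible.

## The scan and the family-wise null

`scan_gene_pair()` tests all $|A| \times |B|$ pairs between the index gene
and one partner gene, in deterministic position order, and summarises to the
gene-level minimum p over converged pairs (ties all reported). Genes are
defined as the most inclusive transcript interval padded by 10 kb on both
sides (0-based half-open arithmetic; a SNP exactly 10,000 bp upstream of the
first transcript base is inside, 10,001 bp is out).

Family-wise significance over all pairs and all partner genes uses the
min-p/max-T permutation scheme (`build_null()`): case-control labels are
permuted (genotypes and covariates stay attached to individuals, so every
covariate-outcome association is broken while LD and covariate structure
are preserved), all scans are re-run, and each of the $B$ replicates
contributes its **experiment-wide** minimum p. Each gene's observed minimum
p is then referred to this single null distribution:

* empirical p = (number of replicates with null minimum ≤ observed) / $B$,
  ties counting as exceedances — so 5 exceedances out of 1,000 replicates
  give 0.005, and the value lives on the grid $\{0, 1/B, \dots, 1\}$. The
  add-one estimator $(\#+1)/(B+1)$ is available by flag.
* the significance threshold is the $\lfloor \alpha B \rfloor$-th smallest
  null minimum — with $B = 1{,}000$ and $\alpha = 0.05$, the 50th most
  significant permuted value. A pair is selected if its observed p is
  $\le$ the threshold (ties included).

An experiment-wide null (rather than one null per gene) is the default
because a shared null is what makes mid-strength observed minima (p around
$10^{-5}$ in a family of thousands of tests) come out non-significant after
correction; `null_type = "per-gene"` provides the per-gene alternative.
Permutation is unstratified by default, with stratified-by-site permutation
available via `strata`.

Defaults: $B = 1{,}000$ replicates, $\alpha = 0.05$; per-replicate seeds are
derived from the master seed by fixed offsets and recorded, so the null is
bit-reproducible.

## Replication and the driving-SNP rescan

Pairs passing the threshold are re-tested in the independent replication
cohort with the identical model (`replicate_pairs()`); significance there is
nominal two-sided $p < 0.05$ — the replication family is the short,
pre-selected pair list, so no further multiplicity correction is applied —
and no direction constraint is enforced, though sign concordance with
discovery is always reported. When replication fails, `cross_gene_rescan()`
tests the driving SNPs (the partner-gene SNPs carrying the most selected
pairs) against *all* index-gene SNPs at the nominal level; this output is
labelled exploratory, and a hit there through different index variants is
the allelic-heterogeneity pattern.

## Quality control

Order matters and is fixed: samples with ≥ 5% missing dosages are dropped
first; SNP statistics are recomputed on the survivors; then SNPs are dropped
with first-failing-rule attribution in the order missingness (≥ 5%), MAF
(< 1%, so a SNP at exactly 0.01 survives), Hardy–Weinberg exact p among
controls (< 10⁻⁶), imputation r² (< 0.3). All five cutoffs are arguments of
`qc_thresholds()`. The HWE test is the exact conditional test (heterozygote
counts no more probable than observed, given allele counts), computed by the
standard recurrence and verified in the suite against full enumeration;
genotypes are hard-called from dosages by rounding halves away from zero —
the desk-scale analogue of testing pre-imputation genotypes, and documented
as such. The minor-allele orientation is normalised once at load time
(dosage flipped to $2 - d$ wherever the stored allele frequency exceeds
0.5, with the flip recorded), so every downstream effect is on the
minor-allele scale.

Candidate partner genes are kept at interaction-confidence score ≥ 0.7
(the conventional "high confidence" cutoff; the boundary is inclusive, and
configurable) and restricted to autosomes, because X/Y dosages are not
comparable between sexes under the autosomal dosage model.

## Ancestry principal components

`eigenstrat_pca()` standardises each SNP column by centring at $2\hat p$ and
scaling by $\sqrt{\hat p(1-\hat p)}$, with the shrunk frequency estimate
$\hat p = (1 + \sum d)/(2 + 2n)$ (plain MLE by flag); missing dosages are
mean-imputed per SNP before the decomposition, constant SNPs are skipped
with a warning, and the top-$k$ eigenvectors of the sample-sample covariance
are the coordinates. $k = 2$ by default. PCs are computed per cohort on the
post-QC SNP set (the replication cohort gets its own PCA; nothing in the
data supports transferring discovery PCs). Optional greedy window LD
pruning is off by default — the synthetic data's LD has limited extent, and
pruning is a data-size decision the caller can make.

## The synthetic-study generator

`simulate_study()` emulates the features of imputed case-control GWAS data
that this analysis is actually sensitive to, with all knobs in
`sim_config()`:

* **LD** (`ld_block_size = 4`, `ld_rho = 0.9`): binary haplotypes are
  thresholded latent Gaussian AR(1) variables within consecutive blocks, so
  genotype $r^2$ decays with index distance inside a block and vanishes
  across blocks. One designated pair is a perfect copy ($r^2 = 1$), shadowing
  the planted partner SNP — mirroring a driving pair in perfect LD — and the
  twin shares its template's *imputed* dosages, so the $r^2 = 1$ survives
  into the fractional data. Block-wise haplotype copying was chosen over
  coalescent simulation because the analysis only needs realistic
  correlation, not genealogical realism.
* **Dosage noise** (`imputation_r2_range = c(0.7, 0.99)`): per SNP, Gaussian
  noise is added to the integer dosage and clipped to $[0, 2]$, with the
  noise scale calibrated against the clipped values so the realized squared
  correlation with the true dosage hits the target; the *realized* value is
  what is recorded, since the QC filter acts on the estimated quality. Two
  background SNPs default to target 0.25 so the r² filter has work to do.
  Note the statistical consequence: phenotypes are generated from true
  genotypes, so scanning noisy dosages attenuates $\hat\beta_3$ toward zero
  exactly as measurement error does in real imputed data.
* **Confounding**: each sample carries two latent ancestry coordinates;
  allele frequencies shift linearly along the first for a configurable SNP
  subset (half the background SNPs at `ancestry_maf_shift = 0.1`, half the
  gene SNPs at half that amplitude), implemented as a two-pool haplotype
  mixture so the shift coexists with block LD. Study site is both a
  phenotypic offset (`site_effects`) and, through a site-dependent shift of
  ancestry coordinate 1, a genetic confounder. Two coordinates are used
  because two PCs are adjusted for.
* **Outcome** (`beta0 = -0.4`, `beta1 = beta2 = 0.1`, `beta3 = log 2`): case
  status is Bernoulli with the logistic model above, evaluated at the
  planted pair — one mid-gene index SNP and one mid-gene partner SNP, placed
  mid-grid so the planted variants have representative (mid-range) minor
  allele frequencies. Cohorts are ascertained retrospectively: a population
  is simulated in batches and the first `n_cases` cases and `n_controls`
  controls are kept, matching the case-control design.
* **Scale**: discovery defaults to 1,000 + 1,000 and replication to
  800 + 1,200 samples, with a 16-SNP index gene, three 10-SNP partner genes
  and 200 background SNPs — the low end of the cohort sizes this design is
  used at, chosen so a full default study with a 1,000-replicate null runs
  in minutes on one CPU.

What the generator does **not** emulate: recombination-map or coalescent
realism, phasing, genotyping-error models beyond dosage noise, rare-variant
frequency spectra, X-chromosome inheritance, and case-control imbalance in
missingness. Passing tests therefore demonstrate the statistical machinery
(calibration, error control, recovery, reproducibility) under a faithful
abstraction of imputed GWAS data — not robustness to artefacts the generator
does not produce.

## Numerical and procedural choices worth knowing

* Child seeds are derived from the master seed by fixed affine offsets
  folded into the 32-bit range, and every stage's seed is recorded in the
  run manifest; identical (config, seed) gives byte-identical output files.
* The demonstration configuration (`demo_config()`) is sized from the Wald
  standard-error scaling so the planted odds-ratio-2 interaction reaches
  $z \approx 5$ and clears the family-wise threshold with high probability
  (2,000 + 2,000 discovery samples); at a few hundred samples an OR-2
  interaction at mid MAF is essentially undetectable after min-p correction.
* Family-wise error calibration in the acceptance suite uses 200 global-null
  experiments (10-SNP index gene vs three 10-SNP partner genes, n = 600,
  B = 200) with no confounding and no covariates: the global-null FWER
  property concerns the permutation machinery itself, and the
  confounder-adjusted size of the Wald test is checked separately (1,000
  simulations, n = 1,000, with site and two-dimensional ancestry structure
  in both genotype frequencies and risk). Problem sizes throughout the
  suite are the package's choice of desk-scale study conditions.
* At toy sizes (n = 8, the exhaustive-permutation equivalence check) a
  sizeable minority of label arrangements separate the outcome perfectly,
  so no converged test exists for them; the exhaustive and Monte-Carlo
  empirical p are compared with those arrangements excluded identically
  from both sides. `build_null()` itself treats a replicate with zero
  converged tests as a hard error, because on realistic data that signals
  pathology, not chance.
* Ties: everywhere a comparison against a threshold or an observed value is
  made, "at least as significant" means $\le$.

## Known limitations

* The Wald p uses the normal reference; at very low minor allele counts the
  likelihood-ratio or score test would be better calibrated, and the
  permutation null partly compensates for this at the family level.
* The generator's linear frequency shift along one ancestry coordinate is a
  convenient stand-in for real population structure; PCA recovers it by
  construction, which is the point, but real cryptic structure is richer.
* Gene-level minima are not adjusted for the number of SNPs per gene other
  than through the experiment-wide null; comparing empirical p across genes
  with very different SNP counts inherits min-p's well-known size bias.
* The X chromosome is out of scope end to end (candidate genes on X are
  excluded), as are multi-allelic sites (the readers error on them),
  haplotype or multi-SNP interaction models, and FDR-style alternatives to
  family-wise control.
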