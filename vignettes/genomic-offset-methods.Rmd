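---
title: "Genomic offsets, GEA scans and their validation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic offsets, GEA scans and their validation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yewoffset)
```

## The problem

Range-wide samples of long-lived trees such as European yew (*Taxus
baccata*) carry a signature of local climate adaptation in their allele
frequencies: at a minority of loci, frequencies follow the climate
gradient rather than the drift-and-migration background. `yewoffset`
implements a complete population-level workflow around that signal:

1. detect climate-associated loci (genotype–environment association, GEA),
2. model the gene–climate relationship with constrained ordination and
   forest-based turnover functions,
3. project each population's modeled genomic composition under its
   reference climate and under a changed climate (a future scenario or a
   common-garden transplant) and report the distance between the two —
   the **genomic offset**, a proxy for expected maladaptation,
4. flag populations that sit off the species-wide gene–climate cline
   (the **genomic discrepancy index**, GDI), and
5. validate the offsets against independent fitness proxies measured in a
   common garden (population BLUPs and a composite trait index).

Because the workflow has many coupled stages, the package ships a
synthetic-landscape generator with *known* adaptive architecture; every
stage is tested against that ground truth.

## Models and procedures

### Genotype handling

Genotypes are coded 0/1/2 (alternate-allele count). Filtering applies, in
order: SNP missingness (> 30% dropped), individual missingness (> 30%
dropped), then a minor-allele-count filter (MAC < 20 dropped) computed on
the retained individuals — the order matters because the allele count
depends on who is left; with 475 diploid individuals MAC 20 is a 2.11%
frequency cutoff. Missing calls are imputed with the modal genotype of
the individual's gene pool (pools from k-means on the leading genotype
PCs; a deliberately simple stand-in for model-based clustering, adequate
because only the imputation consumes the labels). Linkage pruning is a
greedy positional scan within contigs at r² < 0.7 on genotype codes;
SNPs on different contigs are never compared.

### Constrained ordination

`rda_fit()` regresses the column-centered population × SNP frequency
matrix on standardized predictors and eigendecomposes the fitted values
(via SVD). With conditioning covariates both sides are residualized
first, and the reported R² stays a fraction of the *total* response
variance so that the variance partition is additive: the full model's R²
equals the three semipartial ("pure") fractions plus the confounded
remainder, and `variance_partition()` asserts that identity to 1e-10.
Permutation p-values permute the rows of the tested (residualized) block.

Axis scores predicted from climate alone use the stored coefficients and
training standardization, which is what makes offsets and the GDI
well-defined on new climate tables.

### The association scans

* **Mahalanobis scan** (`rda_outliers()`): each SNP's loading vector on
  the first K = 2 constrained axes, measured as *correlations* with the
  axis scores and variance-stabilized (Fisher z) before the Mahalanobis
  distance. Distances are recalibrated by a genomic inflation factor
  (median D² over the χ²₂ median) and converted to Benjamini–Hochberg
  q-values; candidates have q ≤ 0.10. The loading convention is a real
  design decision: raw projection loadings inherit each SNP's variance,
  and under Balding–Nichols drift that mixture makes the null cloud
  heavy-tailed (we measured null false-discovery proportions near 0.5);
  plain correlations are bounded and mask strong clines. Fisher-z
  correlations keep the null homogeneous *and* the adaptive tail
  unbounded — on null landscapes the scan then holds its nominal rate,
  and on oligogenic landscapes it recovers most true loci.
* **Latent-factor ridge scan** (`lfmm_ridge()`): latent factors are the
  leading left singular vectors of the residual of frequencies on
  climate; climate effects are then re-estimated jointly with the
  factors. The per-variable statistics are t-ratios, so p-values use
  F(1, df) rather than a normal reference (df ≈ 21 at 30 populations —
  the difference matters in the far tail that FDR control looks at), and
  BH runs jointly over the whole SNP × variable family so the 10% level
  applies to the candidate list rather than to each variable separately.
  With zero factors and zero ridge the scan reduces exactly to per-SNP
  OLS t-tests, which is how it is unit-tested.
* **Forest importance scan** (`gf_importance()`): one small regression
  forest per SNP; importance is out-of-bag R² (truncated at zero), and
  candidates are the top 5% intersected across 5 independently seeded
  runs. The structure-corrected variant first residualizes the
  frequencies on the latent factors.
* **Consensus**: candidates found by ≥ 2 methods, LD-pruned, form the
  *outlier set*; a *random set* of equal size is drawn from
  never-flagged SNPs frequency-matched in 10 equal-width MAF bins (bins
  short of eligible SNPs widen to their neighbours).

### Offsets, turnover functions and the GDI

`rda_offset()` projects reference and future climates through the model
coefficients and returns the per-population Euclidean distance over the
first K = 2 axes, each axis weighted by its eigenvalue share
w_k = λ_k/Σλ_k. "Weighted by axis importance" admits several readings
(λ, √λ, or the variance fraction); the variance fraction is the default
with `weight = "sqrt"`/`"none"` switches.

`gf_turnover()` builds monotone cumulative-importance step functions per
climate variable: each SNP forest's out-of-bag R² is split over variables
in proportion to impurity importance and, within a variable, spread
evenly over that forest's split points; pooled, sorted and cumulated
(averaged over SNPs) they form the turnover function. `gf_offset()` is
the Euclidean distance between turnover-transformed climate vectors,
clamped to the training range — cumulative importance is undefined beyond
observed splits, so extrapolation saturates at the boundary value.

Offsets are averaged over GCMs, min-max normalized across populations,
and cut into five equal-occupancy classes (ties broken by population
label). Two engines are *congruent* for a population when their classes
differ by less than two; `robustness_flags()` marks the rest.

`gdi_rda()` contrasts observed scores (centered frequency vectors
projected on the axes) with climate-predicted scores, weights axes the
same way, and min-max normalizes the distances. When the response is
exactly linear in climate the raw index is identically zero, which is
tested to 1e-8.

### Spatial eigenvectors

`dbmem()` builds Moran eigenvector maps from haversine distances:
truncation at the longest minimum-spanning-tree edge, distances beyond
set to four times the truncation, double-centered eigendecomposition,
and retention of eigenvectors with positive eigenvalues whose Moran's I
(binary within-truncation connectivity) exceeds the null expectation
−1/(n−1).

### Trait BLUPs and validation

`fit_trait_blups()` fits `value ~ covariates + (1|population) +
(1|genotype)` by REML and returns the predicted population intercepts.
A compact Gibbs sampler with weak inverse-gamma priors (the univariate
analogue of an inverse-Wishart V = 1, ν = 0.002 prior) is available as
`method = "gibbs"`; with weak priors its posterior means track the REML
BLUPs to correlation > 0.99, which is why REML — deterministic and fast —
is the default. Populations with fewer than three measured plants are
excluded. `composite_trait_index()` min-max standardizes each trait's
BLUPs and averages them with equal weights; `validate_offsets()` reports
Pearson correlations and OLS slopes of fitness proxies on offsets, with
negative values the direction expected under maladaptation.

## The synthetic landscape: what it emulates, and what it does not

`simulate_landscape()` generates: two gene pools mixed linearly along an
east–west axis (admixed center); neutral loci as hierarchical
Balding–Nichols draws (pool level at `drift_fst`, population level at
half that); adaptive loci as logistic clines on the first ("driver")
climate variable; within-contig linkage as near-copies of a neighbouring
SNP sharing its generating frequency; missing genotypes at a set rate;
and future climates as the reference plus a per-variable shift with
small per-GCM jitter. Climate variables are AR(1)-correlated Gaussians
(max correlation 0.5) with the driver partially tracking the spatial
axis — predictor selection is exercised but not degenerate, and climate
is realistically confounded with structure.

Default conditions, chosen once: 29 populations × 16 trees × 2000 SNPs
(a desk-scale stand-in for a 29-population, 475-tree, 8616-SNP panel);
5% adaptive loci at logit slope 1.5 per climate SD; `drift_fst` 0.15
(population differentiation in range-wide conifer panels typically spans
0.05–0.3); 5% missing calls; future shifts of (+1.5, +0.3, +0.8, +1.5,
−1.0, +0.5) SD — warmer and drier with stronger seasonality; five GCMs
with 5% jitter; seed 17.

What passing tests on this landscape do *not* show about real data: no
recombination maps or coalescent history (linkage is a caricature), no
selection through time, phenotypes are clean monotone functions of the
true fitness signal plus Gaussian noise, and climate tables are
noise-free. The generator demonstrates that the estimators recover what
they target under their own assumptions — not that those assumptions
hold in any particular forest.

## Numerical and design choices

* Axis-sign indeterminacy: all score comparisons in tests are up to sign.
* Rank deficiency: `rda_fit()` refuses collinear predictors (advising VIF
  pruning); perfectly collinear climate variables get infinite VIF and
  drop first; monomorphic SNPs get zero loading, zero scan statistics and
  zero forest importance, and can never become candidates.
* Forward selection admits a variable only if its permutation p ≤ 0.05
  (candidate rows permuted, partial pseudo-F) and stops when the kept
  set's adjusted R² (Ezekiel) would exceed the full model's — except at
  α = 1, where the caller wants the complete ordering.
* Tie-breaks are deterministic everywhere: modal imputation prefers the
  lowest genotype code, offset classes break ties by population label,
  correlation pruning prefers the forward-selection order.
* Five-class occupancy uses rounded rank boundaries, so 29 populations
  split 6/6/6/6/5.
* The Gibbs option exists for fidelity to Bayesian mixed-model practice;
  all shipped analyses use REML.
* Problem sizes in the test suite and acceptance script (hundreds to
  2000 SNPs, 16–30 populations, tens of seeds) were chosen as the
  smallest sizes at which the statistical properties under test are
  stable; they are the package's own desk-scale study conditions.
* The variance-partition recovery check compares the pure-climate share
  estimated from sampled genotypes against the same partition computed on
  the noiseless generating frequencies — the target is defined by the
  generator itself, so the check isolates genotype-sampling error.
* The cross-engine consistency check (linear vs forest offsets) is run
  in the near-linear cline regime (logit slope 0.5) with spatially
  heterogeneous displacement. Under strongly sigmoidal clines the two
  engines *should* disagree — the forest model concentrates turnover
  where allele frequencies actually move — and under spatially uniform
  displacement the linear offset is constant across populations, so rank
  agreement is undefined. Both regimes are scientifically informative,
  but only the linear one is a consistency check.

## Known limitations

* Offsets are reported only for genotyped populations; no spatial
  interpolation to unsampled locations is attempted.
* BLUP uncertainty is reported but not propagated into the validation
  correlations (a measurement-error model is out of scope).
* The forest turnover functions are step functions supported on observed
  split points; with few populations they are coarse, and offsets beyond
  the training climate range saturate.
* The moment estimator of population-specific FST targets the same
  quantity as Bayesian population-specific models but will not reproduce
  their numerical values; Jost's D uses sample-size-corrected
  heterozygosities and can be slightly negative in small samples.

## A worked end-to-end run

```{r, eval = FALSE}
cfg <- pipeline_config(
  landscape = landscape_config(n_pops = 24, n_ind_per_pop = 10,
                               n_snps = 250, seed = 7),
  seed = 7, n_perm = 99)
res <- run_pipeline(cfg, out_dir = "run1")
report("run1")$candidate_counts
```

The run directory contains the variance partition, per-method candidate
flags, per-population offsets (method × SNP set, with classes), the
discrepancy index, differentiation statistics and a JSON manifest with
the seed and file checksums; rerunning with the same configuration and
seed reproduces every file bit for bit.
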