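---
title: "Methods behind hearQTL: models, parameters and design choices"
author: "hearQTL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind hearQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hearQTL)
```

hearQTL implements a replication workflow for quantitative hearing traits:
derive audiometric endophenotypes, adjust them for sex, age and genomic
relatedness, test candidate SNPs under four genetic-model codings, run a
gene-based test on principal components of intragenic genotypes, filter
discovery-GWAS hits down to candidate genes, and draw genotype-stratified
audiogram profiles. This vignette documents the models, their assumptions,
the tunable parameters, and the places where a genuinely open design choice
had to be made.

## Traits

Air-conduction thresholds are measured in dB at 0.25, 0.5, 1, 2, 4, 6 and
8 kHz; higher values mean worse hearing. Thirteen traits are derived per
individual:

* the 7 single-frequency thresholds;
* three pure-tone averages: low = mean(0.25, 0.5, 1 kHz),
  mid = mean(0.5, 1, 2 kHz), high = mean(4, 8 kHz). 6 kHz belongs to no
  PTA band but does enter the single-frequency traits and the PCs;
* the first three principal components of the 7 thresholds.

The threshold PCA is computed on the **covariance** of the **raw** (not
covariate-adjusted) thresholds. Neither choice is forced by the trait
definitions; covariance preserves the dB scale, on which the statement
"PC1 carries about 80% of the variance" is meaningful for audiograms, and
computing PCs before adjustment keeps the trait definition independent of
the adjustment model. Each component's sign is fixed so its loading sum is
non-negative, making higher PC1 correspond to worse overall hearing and
effect directions reproducible across runs. If the threshold covariance is
rank-deficient the decomposition is still returned (with a warning); only
an identically-zero covariance is an error.

## Trait adjustment and the two-stage association strategy

All association tests use residuals of the mixed model

$$ y = X\beta + g + e,\qquad \mathrm{Var}(g) = \sigma^2_g K,\quad
   \mathrm{Var}(e) = \sigma^2_e I, $$

with $X$ = (intercept, sex, age) and $K$ the genomic relationship matrix
estimated by the centered-and-scaled allele-sharing form
$K_{ij} = M^{-1}\sum_m (g_{im}-2p_m)(g_{jm}-2p_m) / (2p_m(1-p_m))$.
On this scale the diagonal is ~1 and full siblings ~0.5 (twice the kinship
coefficient 1/4). Negative eigenvalues of the estimate are clipped at zero
("bending") with a warning.

REML estimation reparameterizes the covariance as
$\sigma^2_P\{h^2 K + (1-h^2) I\}$ and profiles everything except
$h^2 \in [0, 0.99]$, which is found by `optimize()` (golden-section /
parabolic, tolerance $10^{-6}$) in the eigenbasis of $K$, so one
decomposition serves the whole search. When $K$ carries no information
(e.g. $K = I$) the criterion is flat in $h^2$; the fit warns about
non-identifiability and the fixed effects collapse to OLS.

The adjusted trait is the *environmental* residual
$y - X\hat\beta - \hat g$, with $\hat g$ the BLUP of the polygenic effect
(equivalently $\hat\sigma^2_e V^{-1}(y - X\hat\beta)$). Regressing these
residuals on a genotype is fast but mis-scaled under relatedness, so the
score statistic is divided by a calibration factor: the ratio of the naive
residual-regression statistic to the exact mixed-model score statistic.
Because the numerators of the two statistics coincide when the genotype is
projected orthogonally to $X$, the ratio is deterministic per SNP,

$$ \gamma_c = \frac{\hat\sigma^4_e\, c' P_V c}{\tilde c'\tilde c\,
   \hat\sigma^2_r}, $$

and the package computes it **per tested SNP** from the cached eigen-space
pieces of the fit (an $O(n^2)$ multiply per SNP). A scalar summary per
genetic-model coding, averaged over a random subset of up to 1000 SNPs, is
also estimated, stored on the `AdjustedTrait` and used when the exact
pieces are absent. A single scalar is not quite sufficient in practice:
the ratio varies across SNPs, most visibly for recessive codings of
lower-frequency variants, whose homozygote cells are small and unevenly
spread across families. The per-SNP form keeps all four codings calibrated
(empirically within [0.035, 0.065] at nominal 0.05 in cohorts with 25% of
individuals in sibling pairs and $h^2 = 0.4$) while preserving the limit
$\gamma \to 1$ as $\hat h^2 \to 0$, where every test becomes numerically
identical to plain OLS of the raw trait on (covariates, genotype).

Effect estimates are reported as $\hat\beta/\gamma$ with standard error
$\mathrm{se}/\sqrt{\gamma}$. Two-sided p-values use the large-sample
normal reference by default (cohorts of several hundred justify it); an
exact t reference is available by flag.

## Genetic models and replication

Additive tests use the raw effect-allele dosage; dominant, recessive and
overdominant codings first hard-call dosages at 0.5/1.5. The thresholds
are a transparent choice for imputed data — the coding of non-additive
models on dosages is not otherwise determined — and codings whose smaller
cell holds fewer than 10 individuals are flagged `low_confidence` rather
than suppressed. A SNP replicates when its replication p-value is below
the nominal 5% *and* the effect direction matches discovery; no correction
is applied across the four genetic models, which are strongly dependent
tests of one variant.

## Gene-based test

For each gene: (1) adjust the trait as above; (2) keep intragenic SNPs,
meaning positions inside the annotated interval, inclusive, with no
flanking margin; (3) compute principal components of the genotype matrix
coded 0/1/2 (imputed dosages hard-called; raw-dosage PCA available behind
a flag for sensitivity analysis) and keep components whose variance
fraction strictly exceeds $1/N$, $N$ the intragenic SNP count; (4) regress
the adjusted trait on the selected components jointly and report the
overall F test. If the strict $>1/N$ rule selects nothing (possible only
in degenerate fraction patterns such as a single SNP), PC1 is kept with a
warning so the gene is not silently dropped.

## Candidate-gene filtering

Discovery hits are pruned greedily: repeatedly take the smallest-p
remaining hit and discard all hits within ±250 kb on its chromosome —
the standard clumping semantics, made order-independent by a canonical
sort (p, then position) before the pass. Hits with no annotated gene
within ±250 kb are gene deserts and are dropped; survivors are assigned
their closest gene by edge-gap distance (0 if intragenic) plus, in
multi-gene mode, every further gene inside the window. Genes matching
name-exclusion patterns (`LOC*`, `FAM*` by default) or a user-supplied
disease-exclusion list are removed. Prioritization is flag-driven: a gene
is shortlisted when an antibody is available *and* at least one further
criterion holds (highly suggestive discovery p, hearing-loss gene-family
similarity, inner-ear expression, pathway link, or — by default — a
suggestive discovery p). Criteria flags are inputs; the package queries no
external database.

## Genotype profiles

Profiles stratify age/sex-adjusted thresholds (OLS residuals plus the
grand mean — deliberately *not* kinship-BLUP residuals, since the curves
display covariate-adjusted dB) by hard-called genotype, with A the major
allele. Means and SEs are computed at 0.25, 0.5, 1, 2, 4 and 8 kHz; 6 kHz
is excluded by default to match the profile frequency set, and can be
re-included by flag. Groups under 30 individuals are flagged underpowered
and force classification to `none`.

The pattern classifier replaces visual inspection with one calibrated
contrast: BB minus AA must have a consistent sign at ≥ 5 of 6 frequencies
and an across-frequency average difference exceeding 1.96 × the mean
per-frequency SE of the difference. Averaging the per-frequency SEs
(rather than dividing by $\sqrt 6$) is deliberately conservative whenever
frequencies are positively correlated, as audiogram residuals are. A
significant positive contrast is attributed to whichever homozygote lies
farther from the heterozygote curve — BB deterioration versus AA
improvement — and a negative one is BB improvement. Tying all three
classes to a single gated contrast keeps the null false-call rate at or
below the level of one 5% test; the mirrored "AA improvement" reading of
the same tail would otherwise double-count it. Both constants (5/6
frequencies, 1.96) are exposed as arguments.

## The synthetic cohort generator

`simConfig()` / `simulateCohort()` generate the data every calibration and
power statement in the package is computed on. The model:

* **Genotypes** — two haplotypes per individual from a Gaussian-copula
  AR(1): latent standard normals with lag-one correlation `ld_rho` are
  thresholded at the per-SNP allele-frequency quantile. This is the
  simplest LD model with a closed-form oracle; the analysis needs local
  correlation, not realistic haplotype diversity, so no coalescent
  machinery is used. Note the copula attenuates correlation: latent 0.8
  gives adjacent-dosage $r \approx 0.58$ at MAF 0.3.
* **Relatedness** — sibling pairs only; each pair shares each haplotype
  with probability 1/2 (expected kinship coefficient 1/4). Richer
  pedigrees are out of scope.
* **Audiograms** — baseline curve + age slopes (dB/year, steepening with
  frequency, as in presbycusis) + a male high-frequency penalty + injected
  SNP effects (dB per coded unit, applied at every frequency) + one
  common factor with per-frequency loadings (the correlated
  "susceptibility" component) + a polygenic term drawn multivariate normal
  with covariance $\sigma^2_g A$, $A$ the pedigree-expected relationship
  matrix + independent noise. `h2` is defined relative to the
  polygenic-plus-noise variance. Ages are uniform on [18, 80] (adults
  only); sex is Bernoulli(1/2).

Default parameters describe a rural replication cohort of 493 adults with
common variants (MAF 0.05–0.5), moderate local LD, 60 sibling pairs,
heritability 0.3, and a factor/noise balance (loadings 7–10 dB rising with
frequency, noise 6 dB) under which PC1 carries roughly 80% of the
threshold variance — the structure reported for real audiometric
cohorts. What the generator does **not** emulate: population
stratification, genotyping error, imputation uncertainty structure, chrX,
ear asymmetry, and non-Gaussian threshold floors/ceilings. Calibration and
power results on synthetic cohorts therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to those
real-data features.

Because the polygenic term is family-structured multivariate normal (not
built from the panel SNPs), null SNPs are exactly null — the type-I-error
studies are uncontaminated — but REML against the *genomic* relationship
matrix cannot recover the simulated $h^2$: the GRM's sampling-noise
eigenvectors carry no trait covariance, and the estimate shrinks toward
the family-block information alone. Heritability-recovery studies
therefore fit against `pedigreeRelatedness()`, the exact covariance of
the generative model; association calibration continues to use the
estimated genomic GRM, as the pipeline would on real data.

## Numerical choices and degenerate inputs

* QC thresholds are strict inequalities (MAF < 0.01, Info < 0.4), so
  boundary SNPs are retained; both thresholds are arguments, never
  hard-coded downstream.
* Missing dosages: complete-case per SNP for OLS-adjusted traits;
  mean-imputed for kinship-adjusted traits, whose calibration works in
  the full-cohort eigenbasis. Genotype PCAs mean-impute per SNP.
* Hard-call thresholds 0.5/1.5; values exactly on a threshold call to the
  heterozygote.
* Monomorphic codings yield p = 1 / beta = 0 with an `untestable` flag,
  not an exception; empty genes are flagged, not errors.
* BED input is converted once, on read, to the package's 1-based
  inclusive convention.
* MAF absent from metadata is computed from the sample and folded to
  ≤ 0.5.
* Ties in region pruning are broken by smaller position, then chromosome,
  then SNP id, making the greedy pass deterministic.

## Problem sizes used in the shipped studies

The test-suite and acceptance studies run at the scale the methods are
intended for: calibration on 1000 null replicates (n = 400; a 40-SNP gene
for the gene test; a 2000-SNP panel with 25% of individuals in sibling
pairs and $h^2 = 0.4$ for the SNP tests), effect-size recovery on 200
replicates of n = 1000, heritability recovery on 50 replicates of n = 800
with 200 sibling pairs, power on 200 replicates per effect size, and the
profile classifier on 100 replicates of n = 1000 per condition.

## Known limitations

* The gene-based test's power at a 0.25 SD causal effect in a 40-SNP gene
  (n = 500, latent LD 0.8) sits near one half: roughly ten PCs pass the
  $>1/N$ rule and the F test spreads a single-SNP non-centrality of ~13
  across them. Denser LD concentrates the signal and raises power.
* The scalar per-model gamma is reported but the per-SNP exact ratio is
  what guarantees calibration for sparse codings; users consuming only
  the scalar should restrict recessive/overdominant inference to common
  variants.
* Sibling pairs are the only relatedness structure; the kinship machinery
  accepts arbitrary PSD matrices, but the generator cannot emulate deeper
  pedigrees or cryptic structure.
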