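---
title: "Separating maternal and fetal genetic contributions to quantitative traits in mother-offspring duos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating maternal and fetal genetic contributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Circulating immune mediators measured in pregnant women and in their
newborns sit at an unusual genetic interface: the measured level in either
individual may be shaped by the mother's genome, by the child's genome, or
by both. With genotypes for mother-offspring duos (and no paternal data),
ordinary SNP-based heritability cannot tell these apart, because a child
carries half of each maternal genome: any "fetal" polygenic signal is
correlated with a "maternal" one through transmission.

`dyadherit` implements an analysis chain that resolves this by allele
partitioning. At every SNP where transmission can be deduced, the maternal
genotype is replaced by the single **non-transmitted** maternal allele, and
the offspring genotype by the single allele **not inherited from the
mother** (the paternal allele). The two resulting pseudo-haploid genomes
are, by construction, free of the shared transmitted material: the
non-transmitted maternal allele carries maternal-specific signal
independent of the child's genome, and the non-inherited allele carries
fetal-specific signal independent of the mother's.

## The model

For a prepared phenotype \(y\) on \(n\) individuals with covariates \(C\),

\[ y = C\beta + g + \varepsilon, \qquad
   g \sim N(0, \sigma^2_g A), \quad \varepsilon \sim N(0, \sigma^2_e I), \]

where \(A\) is a genetic relationship matrix (GRM). SNP-based heritability
is \(h^2_g = \sigma^2_g / (\sigma^2_g + \sigma^2_e)\). Variance components
are estimated by restricted maximum likelihood (REML) with
average-information (AI) updates; when an AI step cannot increase the
restricted likelihood the update falls back to Fisher scoring (expected
information). Because both V and the projection reduce to diagonal algebra
after one eigendecomposition of \(A\), each fit costs little beyond that
decomposition, which makes the 100-fold permutation nulls cheap.

Two GRM estimators are provided:

* **diploid**: the standard standardized-genotype estimator with the
  variance-corrected diagonal, using sample allele frequencies;
* **haploid no-dosage-compensation (ND)**: for pseudo-haploid (male
  pseudo-X coded) matrices, the full-dosage-compensation entry
  \(A_{jk} = \frac{1}{m_{jk}} \sum_i \frac{(x_{ij}-p_i)(x_{ik}-p_i)}{p_i(1-p_i)}\)
  halved for every male-male pair, \(A^{ND} = \tfrac12 A\). The ND model
  assumes each allele has a similar effect on the trait.

We apply the ND halving to the diagonal as well: a self-pair is a
male-male pair, and a uniform scalar on the GRM only rescales
\(\hat\sigma^2_g\) while leaving \(h^2_g\)'s likelihood-ratio test
invariant (asserted numerically in the test suite). The off-diagonal-only
behaviour is available behind `nd_diagonal = FALSE`.

The likelihood-ratio p-value for \(\sigma^2_g = 0\) uses the boundary
mixture \(p = \tfrac12 P(\chi^2_1 > \mathrm{LRT})\), the convention of the
standard GREML tooling; significance conventions differ across tools, so
this choice is documented rather than asserted as universal. Genetic
correlations between trait pairs come from a bivariate REML with six
(co)variance components, fitted blockwise in the rotated space; `rg`'s
standard error is delta-method from the inverse average information.

## Phenotype preparation

Immunoassay concentrations are prepared in a fixed order that the tests
pin down: (1) analytes are kept only when strictly more than 60% of values
exceed their limit of detection (LOD); (2) sub-LOD values are replaced by
LOD/√2; (3) natural log transform; (4) candidate covariates are screened by
univariable regressions and kept when nominally associated (p < 0.05) with
at least three mediators; (5) OLS residualization, with outliers masked on
the residual scale at 3 or 4 SD from the mean (computed once, never
re-iterated) and Shapiro-Wilk normality recorded. The log base is a
package choice (natural log); any base shifts residuals by a scalar and is
invariant downstream. Outlier masking on residuals rather than raw values
is the default because extreme residuals, not extreme concentrations, are
what destabilize the downstream linear models; both are available.

## Ancestry

Genetic distance is one minus the mean identity-by-state sharing over
jointly observed SNPs; classical multidimensional scaling (double-centered
Gram eigendecomposition) yields ten principal coordinates used as
covariates everywhere. Signs are fixed by making each axis's
largest-magnitude loading positive, so coordinates are deterministic.
"Homogeneous sub-populations" for the meta-analysis stage are
operationalized as k-means clusters (default 4) of these coordinates under
a fixed seed; the clustering criterion was an open design point and is
configurable.

## The synthetic cohort generator

Because individual-level duo data of this kind are not public, every
downstream stage is exercised on simulated cohorts with known
architecture. The generator draws ancestral allele frequencies uniform on
[0.05, 0.95], per-population frequencies from the Balding-Nichols beta
model at a chosen Fst (clipped to [0.01, 0.99] so markers survive the
MAF ≥ 1% filter by construction), maternal genotypes in Hardy-Weinberg
proportions, and offspring genotypes as one uniformly chosen maternal
allele (recorded as ground truth) plus a paternal allele from the same
population. SNPs are independent given population — the generator makes no
attempt at linkage disequilibrium; LD-dependent behaviour (conditional
analysis, r² estimation) is tested with a dedicated two-SNP haplotype
construction with closed-form r². Maternal-causal and fetal-causal SNP
sets are disjoint by default, mirroring the observation that maternal and
fetal association signals do not overlap; genetic components and noise are
rescaled so realized variance shares equal their targets exactly, which
removes one layer of Monte-Carlo noise from recovery experiments.

Censoring emulates assay limits: below the configured sample quantile
(default 0.1, a conservative default where the real design only bounds
censoring above 40%), concentrations are recorded as LOD/2 — an arbitrary
sub-LOD sentinel, since sub-LOD values are by definition unquantifiable —
with the LOD stored per analyte so the preparation stage has real work to
do. What passing tests show is therefore internal consistency of the
estimators under a clean polygenic model with population structure; they
do not show robustness to LD, assortative mating, batch structure beyond a
screened covariate, or shared environment, none of which the generator
emulates.

## Numerical choices

* REML convergence: absolute restricted log-likelihood change and maximum
  relative component change both below 1e-4, at most 100 iterations;
  components are floored at 1e-6 of the phenotypic variance (an
  unconstrained mode exists for diagnostics).
* AI steps are halved up to 20 times before the Fisher fallback engages.
* A GRM proportional to the identity makes \(\sigma^2_g\) and
  \(\sigma^2_e\) unidentifiable and is rejected with a clear error.
* Identical traits in the bivariate model are a degenerate input (singular
  residual covariance) and return rg = 1 directly with a warning.
* Permutation nulls swap the full phenotype record (phenotype plus its
  covariate row) against the genotypes by default; phenotype-only
  permutation is available.
* Mendelian-inconsistent duo genotypes are set missing per genotype with a
  logged count (an aggregate-rate ceiling aborts), matching the
  missing-code convention used for unresolvable double heterozygotes.

## A property the partition does not have

Excluding double heterozygotes conditions the resolved data on
resolvability, and this induces a *negative* within-dyad covariance
between the resolved non-transmitted and non-inherited alleles (exactly
−1/12 at allele frequency 0.5, by enumeration), even though the underlying
alleles are independent. The test suite checks independence on the
simulator's ground truth and the negative sign on resolved entries. This
is one reason pseudo-haploid variance captures should be read as evidence
of a maternal or fetal genetic contribution rather than as precise
heritability estimates — the same caution that applies to the introduced
missingness among common SNPs.

## Problem sizes

Recovery experiments in the acceptance tests use cohorts of 800 dyads by
5,000 SNPs (50 replicates) for diploid heritability, 600 x 2,000 (25
replicates) for the cross-genetic separation pattern, 500 x 2,000 (25
replicates) for bivariate rg, and a 600 x 5,000 four-population cohort for
scan calibration — sizes chosen to keep Monte-Carlo error well below the
tolerances being asserted while remaining routine on a single CPU.
`scripts/acceptance.R` re-runs the same computations at 10-20 replicates
and writes the headline numbers as JSON.

## Limitations

Single-component REML only (one GRM at a time, as the partitioned design
requires — pseudo-haploid estimates may be inflated by the absent paired
matrix); no mixed-model association scans; no imputation, phasing, VCF
input, or multiallelic sites; matched case-control designs are handled
through covariates only.
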