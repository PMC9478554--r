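---
title: "Genomic prediction for repeatedly measured traits: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction for repeatedly measured traits: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

AngoraGS implements genomic selection (GS) analysis for a breeding
population in which one trait is recorded repeatedly — here at 70, 140 and
210 days of age, the shearing schedule of Angora rabbit wool production.
The population is a single cohort of a few hundred genotyped animals
without reliable pedigree. Three questions drive the design:

1. How many markers are enough? (marker-density subsampling)
2. How heritable are the traits? (REML variance components)
3. Does borrowing information across ages improve early prediction?
   (univariate vs multivariate GBLUP under partial-record cross-validation)

## Models

### Univariate GBLUP

For records $y$ of one trait at one age,

$$y = Xb + Zu + e, \qquad u \sim N(0,\, G\sigma^2_u), \quad
  e \sim N(0,\, I\sigma^2_e),$$

where $X$ carries the intercept, sex and batch (treatment coding, first
observed level as reference; aliased columns are dropped with a warning),
and $G$ is VanRaden's genomic relationship matrix
$G = WW^\top / 2\sum_k p_k(1-p_k)$ built from dosages centred by twice the
in-sample allele frequency. Heritability is
$h^2 = \sigma^2_u/(\sigma^2_u + \sigma^2_e)$.

REML is solved exactly: the phenotyped submatrix of $G$ is
eigendecomposed once, records and design are rotated into the eigenbasis
where the covariance is diagonal, $\sigma^2_e$ is profiled out, and the
variance ratio $\lambda = \sigma^2_u/\sigma^2_e$ is maximized by Brent
search on $\log\lambda$ over $[10^{-6}, 10^6]$. This is deterministic and
has no starting-value sensitivity. The standard error of $h^2$ comes from
the inverse observed information of $(\sigma^2_u, \sigma^2_e)$ (numeric
Hessian of the restricted likelihood) through the delta method. Genetic
variance estimates below $10^{-8}$ times the phenotypic variance are
reported as $h^2 = 0$ with a boundary flag and no SE.

GEBVs are BLUPs $\hat u = \hat\sigma^2_u\, G_{\cdot,\mathrm{obs}}
V^{-1}(y - X\hat b)$ for *every* individual in the GRM; unphenotyped
animals are predicted purely through their genomic relationships. This is
algebraically identical to ridge regression on centred marker dosages with
per-marker variance $\sigma^2_u / 2\sum p_k(1-p_k)$ (SNP-BLUP), which the
test suite verifies against an independently coded ridge solution.

### Multivariate (multi-age) GBLUP

The three ages are treated as distinct traits with

$$\begin{pmatrix}u_1\\u_2\\u_3\end{pmatrix} \sim
  N\!\left(0,\ \Sigma_u \otimes G\right), \qquad
  e \sim N\!\left(0,\ \Sigma_e \otimes I\right)$$

and per-individual residual covariance restricted to that animal's
observed ages, so arbitrary per-cell missingness (the leave-out designs)
enters through each trait's own incidence matrix. Records are never
imputed; missing cells are simply absent from the likelihood — that is
what makes the leave-out strategies meaningful.

Estimation works on the mixed-model equations (MME) over all individuals
in the GRM. Each iteration factorizes the $(3p + 3n)$-dimensional
coefficient matrix. The schedule is:

* **EM burn-in** (8 iterations by default): Henderson's expectation-
  maximization updates, monotone in the restricted likelihood and robust
  far from the optimum. The residual update handles missing cells by the
  missing-data EM: expected complete-data residual second moments combine
  the observed residuals, their conditional extension to unobserved ages,
  and the posterior covariance of $(\hat b, \hat u)$ from the MME inverse.
  Eight iterations are enough to enter the region where Newton-type
  updates are stable; more EM would only slow convergence down, since EM's
  per-iteration gain decays quickly.
* **Average-information (AI) REML** until the relative change in the
  restricted log-likelihood falls below `tol` (1e-8 by default; the
  orchestration functions pass 1e-6 where many fits are run, which moves
  estimates by far less than their sampling error). AI steps use exact
  analytic scores and the average-information matrix, with step halving;
  a step that cannot improve the likelihood falls back to one EM step.
* **Bending**: any proposed covariance matrix is symmetrized and its
  eigenvalues floored at $10^{-6} \times \mathrm{trace}/3$ (with the scale
  taken from the absolute diagonal so a wild proposal cannot collapse the
  floor), keeping every $\Sigma$ positive definite.

Because an in-sample-frequency GRM is exactly singular (rows sum to zero),
the engine adds $10^{-4} \times \overline{\mathrm{diag}(G)}$ to the
diagonal before inverting. The shift adds that fraction of
individual-specific genetic variance — orders of magnitude below the
sampling error of any estimate — and keeps the equations well conditioned;
with a $10^{-6}$ shift the MME inverse loses enough precision that the EM
updates stop being monotone. The univariate path never inverts $G$ (it
only eigendecomposes), so it uses the GRM unmodified.

Non-convergence is a flagged result, never an exception: cross-validation
excludes flagged folds from means and reports the count.

## The evaluation design

* **Corrected phenotypes** $y_c$: OLS residuals of each trait column on
  intercept + sex + batch, computed once on *all* phenotyped individuals.
  Computing them once (rather than per training set) keeps the evaluation
  target fixed across models and densities.
* **10-fold cross-validation**: ids are shuffled under a seed and dealt
  round-robin, so 629 individuals give nine folds of 63 and one of 62.
  The GRM is always built on the full population — information flows to
  validation animals only through genomic relationships, which is the
  mechanism GBLUP exploits. Per fold, validation records are masked
  according to the model's leave-out strategy (uvLMM: the analysed age;
  mvLMM: all three ages; mvLMM23: the last two; mvLMM3: only the last),
  the model is refit, and accuracy is the Pearson correlation between
  $y_c$ and GEBV in the validation set. A leakage guard asserts that no
  masked record appears in any training fit's record list. Accuracy is
  aggregated as the mean of per-fold correlations; pooling predictions
  across folds first is available as a flag (`meanAccuracy(cv, pooled =
  TRUE)`) since both conventions are in circulation.
* **Marker-density scan**: for each density, markers are drawn uniformly
  without replacement (30 replicates by default, each with a recorded
  seed derived from the base seed), the GRM is rebuilt, heritability and
  optionally CV accuracy are re-estimated, and all pairwise correlations
  between the replicate GRMs (vectorized upper triangle including the
  diagonal; excluding it is a flag) measure how stable the relationship
  estimates are at that density.
* **Comparisons** between experimental arms use Welch's two-sample
  t-test (Student's pooled test via a flag); two constant groups compare
  as $p = 1$ when equal and $p = 0$ otherwise, by convention. Fold
  partitions are re-drawn per experiment (unpaired design, consistent
  with a two-sample test); reusing a partition is possible by passing the
  same `FoldAssignment`.

## The synthetic population generator

`simulateGenotypes()` builds haplotypes as first-order Markov chains along
each of 21 chromosomes: marker $k$ copies marker $k-1$ with probability
`ldRho`, otherwise draws fresh from its own Bernoulli frequency (MAF
uniform on [0.05, 0.5]); two haplotypes are summed per individual.
`simulatePhenotypes()` draws `nQtl` causal markers shared across ages
(pleiotropy) with effect vectors from a multivariate normal whose
correlation is the target genetic correlation; induced genetic values and
independent residuals are rescaled **on the realized samples** so that
$\mathrm{var}(u_t)/(\mathrm{var}(u_t)+\mathrm{var}(e_t))$ equals the
target $h^2_t$ exactly, which makes parameter-recovery tests sharp rather
than blurred by simulation noise. Fixed effects are a population mean,
a male/female contrast at the study's 298/331 proportions, and round-robin
batches (the fixed-effect machinery must be exercised even though a single
real cohort may have one batch).

Default conditions mirror the study design: 629 individuals, one trait at
three ages, heritabilities (0.05, 0.30, 0.30) spanning the low-to-moderate
range of wool traits, genetic correlation 0.8 between ages — repeated
measures of a trait are strongly correlated — and a 10,000-marker panel.

**LD calibration.** `ldRho` (default 0.97) is the generator's information
knob: it sets the number of effectively independent chromosome segments,
which controls how precisely $h^2$ can be estimated at a given sample
size. The default was calibrated so that the delta-method SE of $\hat h^2$
at $n = 629$ with the default panel falls in the ±0.04–0.06 band that
genome-wide analyses of this population size report; this corresponds to
a few hundred effective segments and slow LD decay, as expected for a
closed farm population bred from a limited sire pool. With weak LD (e.g.
`ldRho = 0.5`) the same panel behaves like thousands of independent loci,
heritability SEs inflate to ~0.15, and low-$h^2$ estimates pile up against
the zero boundary — a population no 629-animal study could analyse.
The knob also sets which phenomena are visible: once a small panel
saturates the relationship information (very high `ldRho` with few
markers), univariate and multivariate models converge and the
low-heritability borrowing advantage compresses; the model-contrast
experiments in the test suite therefore run at moderate LD
(`ldRho = 0.9`), below that saturation regime, analogous to comparing
models at sub-plateau marker densities.

**What the generator does not emulate:** pedigree/family structure
(mixed-semen insemination surely creates sib groups in the real data, but
pedigree simulation is out of scope, so all information here flows through
LD-driven relationship variation), selection over generations,
coalescent-grade allele-frequency spectra, genotyping/imputation error,
and multi-trait recording beyond one trait at three ages. Passing tests
therefore demonstrate correctness of the estimation machinery under the
stated statistical structure, not robustness to every feature of real
sequencing data.

## Numerical choices and degenerate inputs

* Strict QC comparisons (`MAF > 0.05`, `missing < 0.10`, `HWE p > 1e-6`),
  exactly as printed conventions go; the HWE test is the exact conditional
  test (a chi-squared variant is not offered — on hard calls rounded from
  dosages the exact test is the defensible choice, and the rounding is a
  documented limitation).
* Missing dosages are mean-imputed (twice the allele frequency)
  immediately before GRM construction and never before QC.
* VanRaden method 1 is the default; method 2 (marker-wise scaling) is a
  flag. Monomorphic markers are dropped (or rejected, by flag) since they
  contribute zero to the denominator.
* `stabilizeGRM()` adds a diagonal shift for downstream code that needs a
  positive-definite kinship; the multivariate engine applies its own
  relative shift as described above.
* Correlation of two GRMs with zero variance in either triangle, or
  accuracy over fewer than 3 pairs or with zero variance, is `NA` —
  undefined values are never silently coerced to 0.
* All randomness flows through explicit integer seeds; subsampling,
  folds and simulation are bit-reproducible under a fixed seed.

## Problem sizes used by the test suite

The acceptance-style tests run end-to-end on synthetic populations sized
to finish in minutes on one core while keeping every comparison
well-powered: the parameter-recovery block uses the full study conditions
(n = 629, 10K markers, 200 QTL, 20 seeds); the REML-versus-grid-oracle
block uses n = 300 with 5K markers; the density-trend block subsamples a
200K-marker panel at n = 300; the cross-validation comparisons use n =
250–300 with 3–5 folds and 10 seed replicates. The acceptance script
(`scripts/acceptance.R`) reruns the full pipeline at the default study
conditions and writes its main quantities as JSON.

## Known limitations

* The multivariate engine factorizes dense $(3p+3n)$ equations; it is
  comfortable to n of a few thousand but is not built for national-scale
  evaluations.
* Heritability SEs use the observed information at the optimum; near the
  $h^2 = 0$ boundary the quadratic approximation degrades and the SE is
  reported as `NA`.
* The HWE exact test assumes hard calls; heavily imputed dosages rounded
  to calls can distort it, which mirrors standard practice but is worth
  remembering when filtering low-confidence imputations.
* GEBVs from `predictGEBV()` use the GRM the caller supplies; they agree
  with a multivariate fit's stored GEBVs up to the engine's $10^{-4}$
  stabilizing shift (the shift only applies on the partial-record path —
  the complete-record eigenbasis engine never inverts $G$).
* A single cross-validation at a few hundred animals estimates accuracy
  with a standard error of roughly 0.02–0.05 — the same order as the
  accuracy differences between univariate and multivariate models. Mean
  relationships across replicate experiments (e.g. that the multi-trait
  gain shrinks as heritability grows) are therefore reproducible, but the
  *sign* of such a contrast within any single replicate is not; studies
  that report stable per-trait gains average tens of repeated evaluations
  per point, which is outside this package's test budget.
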