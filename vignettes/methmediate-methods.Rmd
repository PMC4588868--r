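---
title: "Methods: EWAS and mediation of a prenatal exposure effect on birthweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EWAS and mediation of a prenatal exposure effect on birthweight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmediate)
```

## The scientific problem

Maternal smoking during pregnancy lowers offspring birthweight, and it also
leaves a reproducible imprint on cord-blood DNA methylation. `methmediate`
implements the full analysis chain used to ask whether the second fact
explains part of the first: quality filtering of Illumina 450K-style beta
matrices, reference-based estimation of white-blood-cell composition,
a covariate-adjusted epigenome-wide association study (EWAS) of exposure on
methylation, Baron–Kenny mediation of the exposure→birthweight effect through
individual CpGs with Sobel inference, and fixed-effects inverse-variance
meta-analysis across cohorts. A synthetic-data generator with a known
generative truth stands in for cohort data, so every stage is testable
end to end.

## Models

**EWAS.** For each CpG $j$, ordinary least squares of the methylation beta
value on exposure and covariates:

$$\beta_{ij} = \mu_j + \alpha_j\,\mathrm{smoke}_i + \gamma_j^\top z_i + \varepsilon_{ij},$$

where $z_i$ collects sex, gestational age, maternal age, maternal
pre-pregnancy BMI, education (low/middle vs university), plate dummies and
the six estimated cell-type proportions. The exposure coefficient $\alpha_j$
is tested with a Student $t$ statistic on $n-k$ degrees of freedom
(two-sided). Multiplicity is controlled with Benjamini–Hochberg FDR over all
tested probes; a fixed genome-wide threshold $p < 10^{-7}$ is the default
Bonferroni-style convention for 450K-scale panels, with the exact $0.05/m$
flag also reported. We deliberately use ordinary rather than
empirical-Bayes-moderated $t$ tests: at cohort sizes in the hundreds the
moderation of the residual variance changes the $p$-values negligibly, and
the coefficients are identical.

**Mediation.** For a mediator CpG $M$ and birthweight $BW$, three nested OLS
models on one identical sample set:

* $M = \beta_a\,\mathrm{smoke} + \text{covariates}$
* $BW = \beta_c\,\mathrm{smoke} + \text{covariates}$
* $BW = \beta_{c'}\,\mathrm{smoke} + \beta_b M + \text{covariates}$

The indirect effect is $\Delta = \beta_c - \beta_{c'}$, which for nested
linear models fitted on the same rows equals the product $\beta_a\beta_b$
exactly. `fit_mediation()` asserts this identity to relative tolerance
$10^{-8}$ on every call; enforcing complete cases once, before all three
fits, is what makes it hold. The proportion mediated is reported in the
product form $\beta_a\beta_b/(\beta_a\beta_b + \beta_{c'})$, documented equal
to $\Delta/\beta_c$ under the identity. The Sobel statistic is

$$z = \frac{\beta_a \beta_b}{\sqrt{\beta_a^2\,SE_b^2 + \beta_b^2\,SE_a^2}},$$

referred to the standard normal (classical Sobel, known to be conservative;
the tests assert it is not anticonservative). Methylation enters as a
proportion in $[0,1]$, so $\beta_b$ reads as grams per 100% methylation.
Mediation records are reported for every probe regardless of whether the
Baron–Kenny step conditions hold; boolean flags say which do. When a
`paternal_smoking` column with any variation is present it is added as a
covariate automatically — the convention used for replication cohorts, where
the unexposed group is not screened on paternal smoking.

**Cell-type deconvolution.** Houseman-style constrained projection: the
probes with the largest between-cell-type variance in a reference signature
panel (default $k = 100$) are selected, and each sample's betas at those
probes are regressed on the signature by nonnegative least squares
(Lawson–Hanson). Only nonnegativity is imposed, not sum-to-one: the fitted
proportions then carry independent information per type, so all six can be
entered simultaneously as regression covariates without being exactly
collinear with the intercept. A `renormalize` flag rescales to sum 1 for
users who want compositions.

**Meta-analysis.** Fixed-effects inverse variance: $w_i = 1/SE_i^2$,
pooled effect $\sum w_i e_i / \sum w_i$, pooled SE $1/\sqrt{\sum w_i}$, and a
two-sided normal $p$. When a cohort supplies only an effect and a two-sided
$p$ — the situation when pooling published numbers — the SE is recovered as
$|e|/\Phi^{-1}(1-p/2)$, computed in the upper-tail form so it stays accurate
for $p$ down to the underflow limit. Mediation is declared replicated when
the replication-only meta and the joint meta are both two-sided significant
at 0.05.

## The synthetic-data generator

`simulate_cohort()` draws, per sample: cell-type proportions from
group-specific Dirichlet distributions; baseline methylation as the
reference signature mixed by those proportions; planted exposure shifts at
the true CpGs; and clipped Gaussian probe noise. Birthweight is a direct
exposure effect plus the mediator CpGs' *realised* betas times their
gram-per-beta effects, plus covariate effects and Gaussian noise — exactly
the causal structure the mediation model assumes.

Defaults are the study conditions the package is designed around:

| parameter | default | rationale |
|---|---|---|
| group sizes | 129 exposed / 126 unexposed | discovery-cohort sizes |
| planted shift | −0.105 beta at `cg09935388` | top replicated mediator CpG |
| mediator effect $\beta_b$ | 1190.4 g per unit beta | discovery estimate |
| direct effect $\beta_{c'}$ | −143.3 g | discovery estimate; total ≈ −264 g |
| Dirichlet concentrations | granulocyte-dominated, exposed group skewed | makes cell composition a real confounder |
| `noise_sd_beta` | 0.02 | array-level technical noise |
| `mediator_sd_beta` | 0.09 | see below |
| `noise_sd_outcome` | 450 g | puts the total-effect model $R^2$ near 0.3 |
| cigarettes/day | discrete, median 10, range 1–30 | reported distribution |
| missing covariates | 2% of GA, BMI, education entries | matches the handful imputed in practice |

`mediator_sd_beta` deserves a note. Technical array noise alone (sd 0.02)
leaves a mediator CpG with almost no within-group variance, and then
$\beta_b$ is essentially unidentifiable — its standard error is several times
the effect. Real smoking-responsive CpGs vary substantially between
individuals within exposure groups, and it is that biological variation,
transmitted to the outcome, that powers step (iii) of Baron–Kenny. Back of
the envelope: $SE_b \approx \sigma_{BW}/(\mathrm{sd}(M)\sqrt{n})$, so a
within-group mediator sd near 0.09 reproduces an $SE_b$ of a few hundred
grams at $n = 255$, the order reported for the discovery cohort. The
generator therefore adds N(0, 0.09²) individual variability at the mediator
CpGs.

All randomness flows from one seed: the master seed is split into
independent sub-seeds (via `sample.int` under the master seed) for
reference, annotation and each cohort, and an identical configuration and
seed reproduce every file bit-identically.

What the generator does **not** emulate: probe type I/II chemistry and
normalization artefacts, spatial/batch structure beyond a plate label,
correlated CpGs within a gene (planted CpGs are independent given the cell
mixture), bimodal beta distributions at fully (un)methylated loci, and any
genetic effects on methylation. Passing tests therefore demonstrate that the
statistical machinery is correct under the assumed model, not that the model
captures every feature of array data.

## Quality control

A sample is kept when at least 99% of its probes have detection
$p < 0.05$ (strict `<` at the cutoff, `>=` at the fraction — the wording of
the filter rule); a probe is kept when it is assay-class, autosomal, and
detected in at least 99% of the retained samples. Sample filtering runs
first, and probe detection fractions are computed over retained samples; the
alternative ordering is exposed as `probe_filter_first = TRUE`. One boundary
remark: because the probe filter also removes perfectly detected control and
sex-chromosome probes, re-running the *sample* filter on the filtered matrix
can drop borderline samples that originally sat exactly at 99% — each filter
is idempotent on its own output, but the composition is not re-entrant at
the boundary. Missing covariates are singly imputed (mean for continuous,
mode for the binary education indicator, configurable per covariate), with
provenance columns flagging imputed entries. Sex-cluster checks on raw
intensities are out of scope; raw-intensity data never enters the package.

## Numerical choices

* One QR decomposition of the shared design serves every probe in
  `run_ewas()`; `fit_probe_model()` fits the same model through `lm()` and
  the two paths are cross-checked in the tests.
* Exact fits (zero residual variance) report $SE = 0$ and $p = 0$ (or
  $p = 1$ for a zero coefficient) instead of NaN.
* Rank-deficient designs are refused with the aliased columns named, rather
  than silently dropping columns.
* Matrices are written as TSV with `%.17g` formatting and read with a
  correctly rounded parser, so write–read round-trips are bit-identical.
* Probe-selection ties are broken by row order; the NNLS solver is
  deterministic and needs no seed.
* Beta clipping to $[0,1]$ after noise is monitored: the truth record stores
  the clipped fraction, and the default configuration keeps it below 1%.
  Planted shifts whose *expected* betas leave $[0,1]$ by more than the clip
  tolerance are rejected as invalid rather than silently clipped.

## Problem sizes used by the test-suite and acceptance script

The shipped checks run at desk scale, chosen so the whole suite completes in
well under a minute: 300–5000 probes, cohorts of 80–1423 samples, 2000
replicates for coverage checks, 10 000 replicates for the Sobel
type-I check, and eight replicate cohorts per mediated-fraction level at a
pooled $n = 1400$. Genome-wide hit *counts* (how many CpGs clear FDR or
Bonferroni in the real cohorts) depend on the unavailable cohort data and
are not reproduced — the package reproduces the published arithmetic and
pooling exactly, and recovers planted truths statistically.

## Known limitations

* Baron–Kenny with a Sobel test is the implemented inference; counterfactual
  causal mediation (exposure–mediator interactions, sensitivity analysis) is
  out of scope, though `interaction_check()` tests the no-interaction
  assumption the linear decomposition relies on.
* The fixed-effects meta assumes one common true effect; no heterogeneity
  statistics are reported.
* Reference-based deconvolution is only as good as the reference panel; the
  synthetic panel is a stand-in, not a sorted-cell dataset.
* Single imputation of covariates understates their uncertainty; with the
  per-mille missingness rates targeted here that bias is negligible, and the
  complete-case comparison is one flag away.
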