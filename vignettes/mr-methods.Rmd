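---
title: "Methods: Mendelian randomization with mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`mrpipe` estimates the causal effect of a quantitative exposure (height,
in the motivating design) on a binary outcome (atrial fibrillation) using
genetic variants as instrumental variables. A variant j with per-allele
effect $\beta_{x,j}$ on the standardized exposure and $\beta_{y,j}$ on the
outcome log-odds identifies the causal log-odds ratio per exposure SD
through the Wald ratio $\beta_{y,j}/\beta_{x,j}$, provided the three
instrumental-variable assumptions hold: the variant is associated with the
exposure (relevance), shares no confounder with the outcome, and affects
the outcome only through the exposure (exclusion restriction). The package
implements the standard estimator battery whose differing assumptions
about exclusion-restriction violations are the point of the sensitivity
sequence:

- **IVW** pools Wald ratios with weights $w_j = (\beta_{x,j}/se_{y,j})^2$,
  exact when all instruments are valid. The default is multiplicative
  random effects: the fixed-effect SE is inflated by
  $\max(1, \sqrt{Q/(k-1)})$, with $Q$ Cochran's statistic on the ratios.
  Fixed effects are available; with one variant IVW reduces to the Wald
  ratio. The study-standard defaults (genome-wide threshold $5\times10^{-8}$,
  clumping window 10,000 kb at $r^2$ 0.001) govern instrument
  construction.
- **MR-Egger** regresses $\beta_y$ on $\beta_x$ (variants oriented so
  $\beta_x \ge 0$) with an unconstrained intercept; the slope remains
  consistent under directional pleiotropy satisfying InSIDE, and the
  intercept estimates the mean direct effect. SEs carry a multiplicative
  overdispersion factor floored at 1; p-values use $t_{k-2}$.
- **Weighted median** is consistent while valid instruments hold >50% of
  the weight; the SE comes from a seeded parametric bootstrap (default
  1,000 draws) of the per-variant effects.
- **MR-PRESSO** simulates the no-pleiotropy model (default 5,000 draws,
  seeded) to test the leave-one-out residual sum of squares globally,
  flag per-variant outliers (Bonferroni at 0.05), and compare the raw and
  outlier-corrected IVW estimates (distortion). Empirical p-values are
  bounded below by $1/(n_{sim}+1)$.
- **Multivariable MR** fits weighted least squares of outcome effects on
  several exposures' effects without intercept, estimating direct effects;
  the orchestration layer first screens confounder traits in bivariate
  models and then fits one combined model of the traits with bivariate
  direct-effect p < 0.05.
- **Bidirectional MR** rebuilds the instrument in each direction from the
  study significant for that trait.

Estimates are carried on the log-odds scale; odds ratios and 95% CIs
(normal quantile 1.959964) are attached at the reporting boundary, and
`scale_per_unit()` rescales per-SD estimates to natural units (e.g. per
10 cm with the UK Biobank height SD 9.28 cm — note the published per-10cm
lower bound reproduces only from unrounded inputs, so the worked example
checks the estimate and upper bound).

Instrument strength uses $R^2 = 2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2$
(betas per SD; a `trait_sd` flag rescales raw-unit betas) and
$F = R^2(N-2)/(1-R^2)$. Sample-overlap bias uses the first-order
approximation $\mathrm{bias} = \mathrm{overlap} \times
\mathrm{confounded\ effect} / \bar F$, with the confounded observational
effect a user input (default 0.2 SD) and a normal approximation for the
induced type-I error at a supplied estimator SE (default 0.05).

## Individual-level analyses

The GRS is the dosage-weighted sum of effect alleles, standardized within
the cohort. Two-stage MR follows the literal published procedure: stage 1
regresses the exposure on the standardized GRS plus age, sex and 6
principal components (plus model covariates) **among outcome-negative
individuals only**; stage 2 fits logistic regression of the outcome on the
stage-1 prediction (computed for everyone) with the same covariates and
HC1 sandwich SEs, rescaled to per-SD using the whole-cohort exposure SD.
Covariate sets are nested (base; plus twelve clinical diagnoses; plus left
atrial diameter on its complete-case subset), and an echo-subset
sensitivity rerun fits all models on the identical complete-case rows.
Predictor substitution in a logistic second stage carries a small
non-collapsibility attenuation (of order a few percent at these effect
sizes); the recovery benchmark therefore checks the planted effect within
0.05 on the log scale rather than to Monte-Carlo precision.

PheWAS maps diagnosis codes to phecodes, assigns case status at ≥2 code
occurrences (configurable; the upstream "default mapping parameters" are
not enumerated anywhere authoritative), excludes exclusion-range carriers
and sub-threshold carriers from controls, and fits one logistic model per
phenotype (predictor + age + age² + sex + 10 PCs), skipping phenotypes
with <20 cases and non-convergent fits with logged reasons. PheWAS uses
10 PCs and the detailed MR models 6, both exposed as configuration, the
choice mirroring a priori versus scree-based selection.

## The synthetic-data generator

`simulate_cohort()` draws Hardy–Weinberg genotypes at independent variants
(spaced 20 Mb apart over 22 chromosomes, so they are unlinked by distance
and, in expectation, by empirical $r^2$), builds the exposure from a
per-variant effect vector scaled to a configured jointly-explained
variance share, and draws the outcome from a logistic model whose
intercept is solved numerically for the target prevalence. Direct
(pleiotropic) variant effects can be none, balanced, or directional, and
are defined in the exposure-increasing allele orientation — the convention
under which a directional mean is what the Egger intercept estimates.
Default conditions mirror the motivating study at desk scale: 200
variants explaining 11.2% of exposure variance, causal OR 1.34 per SD,
exposure GWAS n = 20,000, outcome GWAS 2,000 cases / 8,000 controls drawn
under case–control ascertainment, a 6,000-person outcome-enriched cohort
(prevalence 0.46, height 170 ± 11 cm) with clinical covariates, PCs
(independent standard normals — no population structure), and left atrial
diameter associated with height and outcome, missing for ~57% of rows.
Outcome-specific variants (no exposure effect) can be planted as
instruments for the reverse direction. Everything is a deterministic
function of the configuration and seed.

`simulate_mr_summary()` is the parametric summary-level counterpart:
observed effects drawn around their truth with the SEs implied by the GWAS
sample sizes (linear for the exposure, case-control log-odds for the
outcome). Because a replicate costs microseconds, recovery grids run at
the published sample sizes (exposure N = 693,529; 65,446 cases / 522,744
controls) rather than at a reduced scale — this is the standard device in
the MR methods literature. What the generator does **not** emulate: LD
block structure (variants are exchangeable and independent), realistic
minor-allele-frequency spectra, population stratification, assortative
mating, or EHR coding noise. Passing recovery tests therefore demonstrates
correctness of the estimators under their own assumptions, not robustness
to those real-data complications.

## Validation-grid design choices

- IVW recovery: true OR ∈ {1.0, 1.34, 2.0}, 200 instruments, 200
  replicates; bias tolerance 0.02 (log scale), coverage ≥ 90%.
- Egger: directional pleiotropy mean 0.02 (SD 0.01), 200 replicates;
  intercept within Monte-Carlo error (three standard errors, floored at
  0.003 for the known weak-instrument intercept bias at finite spread).
- Weighted median: a contaminated design with exactly 40% invalid
  instruments (direct effects ~0.05) among 50 strong instruments (30%
  variance explained, outcome GWAS 200k/800k). The weighted median's
  asymptotic value under one-sided contamination sits at the
  $0.5/(1-p_{invalid})$ quantile of the valid ratio distribution, so the
  demonstration requires per-variant ratio noise small relative to the
  contamination shift; with weak instruments no median-type estimator
  would look robust. Tolerance 0.05 with IVW required to be at least
  twice as biased.
- MR-PRESSO: 50 instruments, 2,000 simulations per replicate, 100
  replicates; a planted 10-SE outlier must be flagged in ≥95% of
  replicates and clean data must yield no outlier in ≥90%.
- Two-stage MR: 100 cohorts of 6,000 with planted OR 1.75 per SD.
- PheWAS: 100 null phenotypes per replicate at n = 2,000 (familywise
  error compared to α plus two binomial standard errors — an empirical
  check of a probabilistic bound needs sampling slack); power for a
  planted OR 1.5 phenotype at n = 6,000 against the study-scale threshold
  0.05/1,816.

These problem sizes keep the full grid to a few minutes while leaving
Monte-Carlo error well below the tolerances; they are stated here so the
whole validation is reproducible from the configuration alone.

## Numerical and policy choices

- Clumping ties on p-value break by (chromosome, position, id); the window
  is inclusive (±window kb); variants absent from the LD panel count as
  unlinked with a warning; indels and multi-allelic records are rejected
  at read time.
- Palindromic variants use frequency inference with ambiguity limit 0.42
  (both studies' frequencies must fall outside [0.42, 0.58]), otherwise
  they are dropped; every harmonization action is recorded per variant.
- Monomorphic variants in the simulator's GWAS emit beta 0 with a sentinel
  large SE and are flagged rather than dropped.
- A confounder study that lacks an instrument variant cannot trigger its
  exclusion (retain-and-log).
- All stochastic operations (weighted-median bootstrap, MR-PRESSO,
  simulators) take explicit seeds; sub-seeds are derived arithmetically
  and kept below 2³¹.

## Limitations

The estimators assume two independent samples unless the overlap
diagnostic is consulted; no correlated-instrument (generalized) IVW, mode
estimators, or contamination-mixture methods are provided. The PheWAS
ships only a ~30-phenotype synthetic demonstration map, not any
proprietary phecode table. Real-data idiosyncrasies (genome builds,
liftover, imputation quality) are out of scope: summary statistics are
assumed pre-cleaned to the canonical column set.
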