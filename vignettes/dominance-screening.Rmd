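---
title: "Methods: dominance-deviation screening and dominance-aware polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance-deviation screening and dominance-aware polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domdev)
```

## Overview

`domdev` tests trait-associated variants for non-additive (dominance)
allelic effects and measures the consequences of ignoring such effects when
building polygenic risk scores (PRS). The pipeline was designed around a
two-sample biobank study of refractive error: a large discovery sample in
which myopia status is *inferred* from the age of onset of spectacle wear
(AOSW), and a smaller replication sample with autorefraction-measured
refractive error in dioptres. Because such cohort data are access-gated,
the package ships a first-class synthetic-cohort generator so that every
stage — phenotype inference, association testing, two-stage screening, PRS
evaluation, and the accuracy-loss simulation — is testable end to end.

## Genotypic-value parameterisation

Throughout, a variant's genotypic value is
`value(g) = beta * g + gamma * 1{g == 1}` with `g` the minor-allele count.
`gamma` is the *dominance deviation*: the heterozygote's departure from the
additive midpoint. Complete dominance of the minor allele means the
heterozygote equals the minor homozygote, i.e. `gamma = beta`; complete
recessiveness means `gamma = -beta`. This single parameterisation drives
the simulator (`variant_panel()` modes), the fitted models, and the PRS
weights, so the same `gamma` means the same thing everywhere.

The association models are (1) the dominance-deviation regression of the
outcome on `snp_add + snp_domdev + covariates` (logistic for binary myopia,
linear for refractive error), and (2) the genotypic regression with the
genotype as a factor, heterozygote reference. Both are saturated in
genotype, hence exact reparameterisations; the test suite asserts their
optimized log-likelihoods agree to 1e-6, and that the contrasts map as
`AA−AB = −(beta+gamma)`, `BB−AB = beta−gamma`. Wald tests (two-sided normal
approximation) are used for every reported p-value; the reference analysis
reports coefficient/SE/p triplets, which is the Wald convention, and the
choice is fixed package-wide for comparability.

## The two-stage screen

Discovery: a variant is *nominally non-additive* when the dominance
deviation has p < 0.05, and *consistent with complete dominance or
recessive action* when **either** heterozygote contrast (AA-vs-AB or
BB-vs-AB) has p > 0.05. Variants passing both are forwarded. Replication:
the linear dominance-deviation model on refractive error, judged at
Bonferroni α / n_forwarded (and nominally, reported separately). The
stricter discovery threshold α / panel size is computed and reported but
plays no role in forwarding — forwarding is nominal by design.

One property of this operational definition deserves emphasis: for a truly
dominant variant, the matching heterozygote contrast (BB-vs-AB under
dominance of the minor allele) is *exactly null*, so its p-value is
uniform and the variant fails the consistency criterion with probability α
at **any** sample size. "Perfect" recovery of a dominant panel is therefore
a (1−α)^m event per cohort draw, not a certainty; the acceptance test for
the 3-dominant-variant construction runs three independently seeded cohort
pairs and requires a majority to be exact, alongside the parts the
construction does guarantee (decisive non-additivity and Bonferroni-level
replication of everything forwarded).

## AOSW-based myopia inference

In replication individuals with both phenotypes, myopia (refractive error
at or below the `myopia_cut`) is regressed on AOSW by logistic regression;
two cuts are then read off the empirical ROC: the least extreme predicted
probability achieving ≥ 90% specificity (the "myopic" call) and the least
extreme retaining ≥ 90% sensitivity (the "non-myopic" call). Probabilities
strictly between the cuts are unclassifiable, and such individuals are
excluded from discovery association fits. Ties are broken toward the cut
maximizing the complementary metric, which makes the procedure
deterministic and order-invariant. When data are separable the two criteria
can cross; the cuts are then collapsed to the specificity cut so the label
partition stays well defined and nothing is unclassified.

Design choices that the source procedure leaves open, and this package's
defaults:

* **`myopia_cut = -0.75` D** mean spherical equivalent — a common
  epidemiological definition of myopia; configurable, and flagged here
  because published variants of the procedure use cuts from −0.5 to −1.0 D.
* **Linearity in AOSW** on the log-odds scale (a plain logistic model).
* **Never-wearers** enter classification through a sentinel late-onset AOSW
  (default 60 years), making them non-myopic *candidates* rather than
  automatic non-myopes.

## The synthetic cohort generator

The generator states a world and keeps it fixed:

* **Sample structure**: discovery n = 228,423 (AOSW only) and replication
  n = 73,577 (refractive error, plus AOSW where "worn") by default.
* **Variant panel**: 146 variants, MAF ~ Uniform(0.03, 0.5) — the screening
  inclusion filter is MAF > 0.03 — and additive effects with |β| ~
  Uniform(0.02, 0.33) dioptres per allele, random sign. The absolute effect
  scale is immaterial because the genetic component is rescaled to a target
  variance fraction; only the joint MAF–effect distribution matters. A
  tab-separated panel file can override every column when externally
  estimated values are available.
* **Genotypes**: independent Binomial(2, MAF) draws (Hardy–Weinberg, no
  linkage disequilibrium — deliberate, matching the simulation design being
  reproduced). The draw is a compiled inverse-CDF kernel on R's RNG stream,
  so everything is reproducible from one integer seed.
* **Refractive error**: mean −0.25 D, SD 2.7 D (UK-adult-like), with the
  panel jointly explaining `genetic_r2` (default 6%, the order of magnitude
  a ~146-variant PRS explains) and small age/gender effects so the PRS
  baseline model is non-trivial.
* **AOSW link**: ever-wearing probability increases with myopia severity
  (logistic in refractive error), and wearers' AOSW = 16 + 2.2 × RE + noise
  (SD 5 y), rounded and clamped to 5–60 years — a monotone, noisy,
  earlier-onset-when-more-myopic link. These constants were chosen once as
  plausible for spectacle-wear epidemiology; they are configuration, not
  calibration.

What the generator does **not** emulate: linkage disequilibrium,
imputation-uncertainty structure beyond dosage hard-calling, genotype
missingness mechanisms, ascertainment of who answers the AOSW question,
non-Gaussian refractive-error skew, and age cohort effects. A green test
therefore establishes that the *procedures* behave as specified on data
satisfying their assumptions, not that the original cohort estimates would
be reproduced; the gated real-data coefficients and the 6.01/5.92/6.04%
real-data PRS variance figures are explicitly out of reach by design.

## PRS construction and evaluation

PRS #1 uses additive-only discovery refits (γ ≡ 0); PRS #2 the joint
(β, γ) from the full dominance-deviation fit for all variants; PRS #3 the
joint weights for a selected robust subset only, additive weights
elsewhere. Weights estimated on the binary (log-odds) discovery scale are
applied unchanged to predict the continuous replication trait — faithful to
the reference procedure, and harmless for a variance-explained metric,
which is scale-free. Missing genotypes contribute the variant's sample-mean
coding values, keeping n constant across scores. Evaluation is the
adjusted-R² increment over `outcome ~ age + gender`, with a percentile
bootstrap over individuals (BCa was not used: the statistic is smooth, the
samples are large, and percentile keeps the procedure simple and exactly
reproducible); the bootstrap type, count and seed are recorded in the
result object.

## The accuracy-loss simulation

Per replicate: fresh training and test sets (default 75,000 each) at 146
panel MAFs; phenotypes under an additive (`β·g`) or completely dominant
(`2β·1{g≥1}`, minor allele dominant — the direction is a configuration
choice since either reading is defensible) architecture, with the genetic
component rescaled so the panel explains exactly the target fraction
(0.02–0.12) of unit total variance; per-variant weights estimated in
training by closed-form single-variant OLS (no covariates exist in this
design), with or without the dominance term; test-set accuracy is the
squared Pearson correlation between score and phenotype. Cell summaries are
replicate means with normal-approximation 95% CIs, and the headline
statistic is the relative reduction in accuracy
`(R²_dom-aware − R²_additive) / R²_dom-aware` per level and averaged over
the grid.

Numerical/efficiency choices: within one replicate, a single pair of
genotype and noise draws is shared by all 24 grid cells (generative model ×
scoring model × R² level). Cell means and CIs are unaffected — each cell
still averages independent replicates — while the grid collapses to two
genotype draws plus sufficient-statistic algebra per replicate (identities
`g² = 2g − h`, `g·h = h`, `1{g≥1} = (g+h)/2` reduce all regressions to a
handful of column sums and crossproducts). `run_replicate()` keeps the
literal one-cell-per-seed path. Fresh draws across replicates, and full
determinism from (master seed, replicate index), are preserved.

A first-order closed form supports sensitivity analysis when a panel's
MAF/effect composition differs from any reference run:
`R²_test ≈ s·t / (1 + k·M/(n·s·t))`, with `t` the target fraction, `s` the
capturable share (1 for a correctly specified score; the variance-weighted
`2(1−p)/(2(1−p)+p)` panel average for additive scoring of dominant truth),
`M` the variant count and `k` the parameters per variant. The dominant-truth
grid cells are accepted against this prediction for the realized default
panel, because the original per-variant MAF/effect pairs are not published
in the main text; the additive-truth cells, which are insensitive to the
MAF spectrum, are accepted by CI overlap with the reference values
directly.

## Numerical notes and degenerate inputs

* Logistic fits use IRLS (deviance tolerance 1e-8, max 100 iterations);
  separation and non-convergence produce *flagged* fits that are excluded
  from screening with a recorded reason rather than propagating NaNs.
* A variant with fewer than three genotype classes cannot identify the
  dominance deviation; such fits are flagged `missing_genotype_class`, and
  a forwarded variant in this state in replication is reported *untestable*
  rather than failed.
* Hard-calling uses `|dosage − g| ≤ threshold` with a 1e-9 float guard so
  ties at exactly the threshold distance are called, matching the
  behaviour of the standard conversion tool.
* Minor-allele orientation is fixed on the full sample before any
  discovery/replication split, so coefficient signs are comparable across
  stages; flips are recorded.
* The age covariate is centred before squaring in the synthetic covariate
  block (conditioning only; tests are invariant).

## Known limitations

* No mixed-model/kinship adjustment, interaction terms, multi-allelic
  variants, or binary PLINK parsing (all out of scope by design).
* The type-I-error, coverage and recovery acceptance checks are stochastic
  statements verified at fixed seeds with a-priori error budgets (bands of
  ±2–3 SE, majority-of-three designs); they validate calibration, not
  every possible draw.
* Bootstrap and coverage tests run at reduced n purely for runtime; the
  statistics checked (percentile coverage, adjusted-R² increments) are
  insensitive to this scaling, and the full-size paths are exercised by
  the acceptance grid and the default cohort configuration.
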