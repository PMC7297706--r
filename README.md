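# domdev

Dominance-deviation screening and dominance-aware polygenic scores for
refractive-error GWAS variants.

## The problem

Most genome-wide association studies, and virtually all polygenic risk
scores (PRS), assume purely **additive** allelic effects: each copy of the
minor allele shifts the trait by the same amount. If many trait-associated
variants actually act **dominantly or recessively**, an additive PRS wastes
part of the heritable signal. `domdev` implements the analysis pipeline for
asking, at a panel of known trait-associated variants, (i) *do any variants
show non-additive allelic effects?* and (ii) *how much PRS accuracy is lost
if pervasive dominance is ignored?* — in the concrete setting of refractive
error (dioptres; myopia is the negative tail) in a large two-sample biobank
design where the discovery sample's myopia status must be inferred from the
age of onset of spectacle wear (AOSW).

## The models

With `g ∈ {0, 1, 2}` the minor-allele count, the three genotype codings are

| coding | AA | AB | BB |
|---|---|---|---|
| `snp_add` | 0 | 1 | 2 |
| `snp_domdev` | 0 | 1 | 0 |
| `snp_cat` | category 1 | reference | category 2 |

Per variant *k*, with covariates *C₁…Cₘ* (age, age², gender, genotyping
array, 10 principal components), the package fits

1. **dominance-deviation logistic model** (discovery, binary myopia *Y*):
   `logit P(Y=1) ~ βᵏ·snp_add + γᵏ·snp_domdev + δ₁C₁ + … + δₘCₘ` — the
   two-sided Wald p-value on γᵏ is the screening statistic;
2. **genotypic model**: the same regression with `snp_cat` in place of the
   two genetic terms (heterozygote reference), giving the AA-vs-AB and
   BB-vs-AB contrasts that operationalize "consistent with complete
   dominance or recessive action" (either contrast p > 0.05);
3. **dominance-deviation linear model** (replication, continuous refractive
   error ŷ): the analogue of (1) by least squares.

Models (1) and (2) are reparameterizations of one another (both saturated in
genotype); the package tests this identity to 1e-6 in log-likelihood.

The **two-stage screen** forwards variants with nominal non-additivity
(p < 0.05 on γ) *and* dominant/recessive consistency in discovery, then
retests them on refractive error in replication with Bonferroni correction
(α / n_forwarded; 0.05/146 = 3.42×10⁻⁴ and 0.05/8 = 6.25×10⁻³ are the
canonical thresholds, with 8 × 0.05 = 0.4 replications expected by chance).

Three PRS constructions are provided: **PRS #1** (additive weights only),
**PRS #2** (joint (β, γ) weights for all variants) and **PRS #3** (γ only
for a selected robust subset). Performance is the incremental adjusted R²
over an age + gender baseline with a percentile-bootstrap CI.

The **simulation engine** reproduces the accuracy-loss experiment: 146
variants, 75,000-individual training and test sets, phenotypes generated
under additive vs completely dominant architectures at total R² 0.02–0.12,
scored with additive vs dominance-aware weights, 100 replicates per cell.
For one dominant variant at MAF *p* the best additive predictor captures
`2(1−p)/(2(1−p)+p)` of its genetic variance (0.889 at *p* = 0.2), which
bounds what the additive PRS can recover.

## Worked example

```r
library(domdev)

panel <- rbind(default_panel(27, mode = "additive", seed = 8),
               variant_panel(paste0("dom", 1:3), maf = c(0.15, 0.25, 0.35),
                             beta_true = c(0.45, -0.4, 0.5), mode = "dominant"))
class(panel) <- c("variant_panel", "data.frame")
pair <- simulate_cohort_pair(cohort_config(
  n_discovery = 12000, n_replication = 6000, panel = panel,
  genetic_r2 = 0.10, seed = 99))

cls <- fit_aosw_classifier(pair$replication$phenotypes$refractive_error,
                           pair$replication$phenotypes$aosw)
cls
#> <aosw_classifier>
#>   logit P(myopia) = 3.8931 + -0.2732 * AOSW   (n = 3180, 1531 myopic)
#>   myopia cut: refractive error <= -0.75 D
#>   p >= 0.7615 -> myopic      (spec 0.928, sens 0.506)
#>   p <= 0.3204 -> non-myopic  (spec 0.566, sens 0.909)

labels <- classify(cls, pair$discovery$phenotypes$aosw,
                   pair$discovery$phenotypes$never_wearer)
scr <- run_screen(pair$discovery, pair$replication, myopia_labels = labels)
scr
#> <screen_result>
#>   30 variants tested in discovery (alpha = 0.05)
#>   nominal non-additive: 5; full dom/rec consistent: 27
#>   forwarded to replication: 5 (expected by chance to replicate: 0.25)
#>   replicated: 3 nominal, 3 after Bonferroni (p < 0.01)
```

The AOSW classifier is fitted on the 3,180 replication individuals with
both phenotypes; its two ROC cuts call 1,577 discovery individuals myopic
with ~93% specificity and leave 2,261 unclassifiable. Of the 30 panel
variants, 5 pass both discovery criteria; exactly the 3 truly dominant ones
replicate (`dom1`–`dom3`, replication dominance p = 4.0×10⁻³, 4.6×10⁻³,
1.3×10⁻⁸), while the 2 forwarded false positives do not — more than the
0.25 replications expected by chance. Note the discovery γ (log-odds of
myopia) and replication γ (dioptres) have opposite signs, as they should.

## Layout

- `R/` — panel/cohort simulation, genotype I/O and codings, AOSW
  classifier, association fits, screen, PRS, simulation grid, CLI.
- `src/` — Rcpp kernel for Hardy–Weinberg genotype draws.
- `tests/testthat/` — module suites, property tests, and
  `test-acceptance.R` (one block per acceptance criterion).
- `vignettes/dominance-screening.Rmd` — methods and design notes.
- `inst/scripts/domdev` — command-line front end (`io-convert`, `simulate`,
  `classify`, `assoc`, `screen`, `fig3`).
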