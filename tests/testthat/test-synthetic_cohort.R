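test_that("variant_panel enforces MAF range and mode consistency", {
  expect_error(variant_panel("v1", maf = 0, beta_true = 0.1, mode = "additive"),
               "v1")
  expect_error(variant_panel("v1", maf = 0.6, beta_true = 0.1,
                             mode = "additive"), "MAF")
  p <- variant_panel(c("a", "b", "c"), maf = c(0.1, 0.2, 0.3),
                    beta_true = 0.2,
                    mode = c("additive", "dominant", "recessive"))
  expect_equal(p$gamma_true, c(0, 0.2, -0.2))
  # heterozygote value equals the relevant homozygote under full dom/rec
  v <- genotypic_values(p)
  expect_equal(unname(v[2, "v1"]), unname(v[2, "v2"])) # dominant: het = minor hom
  expect_equal(unname(v[3, "v1"]), unname(v[3, "v0"])) # recessive: het = major hom
  expect_error(variant_panel("v", maf = 0.1, beta_true = 0.1,
                             gamma_true = 0.05, mode = "additive"),
               "inconsistent")
  expect_equal(nrow(default_panel()), 146)
  expect_true(all(default_panel()$maf > 0.03))
})

test_that("simulate_genotypes is HWE-distributed, sized, and deterministic", {
  p1 <- variant_panel("v", maf = 0.5, beta_true = 0.1, mode = "additive")
  G <- simulate_genotypes(p1, 100000, seed = 11)
  # Binomial(2, 0.5) mean 1, SE of mean = sqrt(0.5/1e5) ~ 0.0022
  expect_gt(mean(G), 0.99)
  expect_lt(mean(G), 1.01)

  panel <- default_panel(146, seed = 2)
  Gm <- simulate_genotypes(panel, 75000, seed = 5)
  expect_equal(dim(Gm), c(75000, 146))
  expect_identical(Gm, simulate_genotypes(panel, 75000, seed = 5))
  # per-variant genotype class proportions within 3 SE of HWE expectations
  q <- panel$maf
  exp_p <- cbind((1 - q)^2, 2 * q * (1 - q), q^2)
  for (cls in 0:2) {
    obs <- colMeans(Gm == cls)
    se <- sqrt(exp_p[, cls + 1] * (1 - exp_p[, cls + 1]) / 75000)
    expect_true(all(abs(obs - exp_p[, cls + 1]) < 4 * se))
  }
  # chi-square goodness of fit non-rejection at alpha = 0.001 (spot checks)
  for (j in c(1, 50, 146)) {
    expect_gt(hwe_chisq_p(Gm[, j], q[j]), 0.001)
  }
})

test_that("simulate_phenotype hits the target variance fraction", {
  p <- variant_panel("v", maf = 0.25, beta_true = 0.3, mode = "additive")
  G <- simulate_genotypes(p, 200000, seed = 21)
  expect_error(simulate_phenotype(G, p, 1.0), "target_r2")
  p0 <- variant_panel("v", maf = 0.25, beta_true = 0, gamma_true = 0,
                      mode = "custom")
  expect_error(simulate_phenotype(G, p0, 0.1), "rescaled")

  y0 <- simulate_phenotype(G, p, 0, noise_seed = 3)
  expect_lt(abs(cor(y0, as.vector(G))), 4 / sqrt(200000))

  y <- simulate_phenotype(G, p, 0.10, noise_seed = 4)
  expect_lt(abs(cor(y, as.vector(G))^2 - 0.10), 0.005)
})

test_that("dominant architecture loses the closed-form variance share to an additive predictor", {
  p <- variant_panel("v", maf = 0.2, beta_true = 0.3, mode = "dominant")
  # oracle: exhaustive 3-genotype enumeration of the variance partition
  share_oracle <- enumeration_additive_share(genotypic_values(p)[1, ], 0.2)
  expect_equal(share_oracle, dominant_additive_share(0.2), tolerance = 1e-12)
  expect_equal(dominant_additive_share(0.2), 2 * 0.8 / (2 * 0.8 + 0.2),
               tolerance = 1e-12)

  G <- simulate_genotypes(p, 200000, seed = 31)
  v <- genetic_component(G, p)
  realized_share <- summary(stats::lm(v ~ as.vector(G)))$r.squared
  expect_lt(abs(realized_share - share_oracle), 0.01)
})

test_that("cohort pair has the default sample structure and is deterministic", {
  cfg <- cohort_config(n_discovery = 8000, n_replication = 5000,
                       panel = default_panel(25, seed = 7), seed = 42)
  pair <- simulate_cohort_pair(cfg)
  expect_s3_class(pair$discovery, "cohort")
  expect_equal(pair$discovery$n, 8000)
  expect_equal(pair$replication$n, 5000)
  expect_length(intersect(pair$discovery$phenotypes$individual_id,
                          pair$replication$phenotypes$individual_id), 0)
  # discovery is AOSW-only; replication carries refractive error
  expect_true(all(is.na(pair$discovery$phenotypes$refractive_error)))
  expect_false(anyNA(pair$replication$phenotypes$refractive_error))
  expect_false(anyNA(pair$discovery$covariates))

  pair2 <- simulate_cohort_pair(cfg)
  expect_identical(pair$discovery$genotypes, pair2$discovery$genotypes)
  expect_identical(pair$replication$phenotypes, pair2$replication$phenotypes)

  # default config mirrors the target design sizes
  dflt <- cohort_config()
  expect_equal(dflt$n_discovery, 228423)
  expect_equal(dflt$n_replication, 73577)
})

test_that("AOSW link strength drives the downstream ROC as expected", {
  base <- cohort_config(n_discovery = 2000, n_replication = 6000,
                        panel = default_panel(10, seed = 3), seed = 9)
  auc <- function(cfg) {
    repl <- simulate_cohort_pair(cfg)$replication$phenotypes
    keep <- !is.na(repl$aosw)
    y <- repl$myopia_true[keep]; a <- repl$aosw[keep]
    # rank-based AUC of (negated) AOSW for myopia
    r <- rank(-a)
    (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
  }
  flat <- base; flat$aosw_slope <- 0; flat$wear_slope <- 0
  expect_lt(abs(auc(flat) - 0.5), 0.05)
  sharp <- base; sharp$aosw_slope <- 8; sharp$aosw_sd <- 1e-6
  expect_gt(auc(sharp), 0.97)
})
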