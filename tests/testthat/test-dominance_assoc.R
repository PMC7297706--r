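test_that("wald_p follows the two-sided normal convention", {
  expect_equal(wald_p(0, 1), 1)
  expect_equal(wald_p(1.959964, 1), 0.05, tolerance = 1e-5)
  expect_equal(wald_p(6, 1), 2 * pnorm(-6), tolerance = 1e-12)
  expect_equal(2 * pnorm(-6), 1.973175e-09, tolerance = 1e-4)
  expect_error(wald_p(1, 0), "positive")
  expect_error(wald_p(1, -2), "positive")
})

test_that("dominance-deviation and genotypic models are reparameterizations", {
  # both are saturated in genotype, so optimized log-likelihoods must agree
  for (seed in 1:8) {
    set.seed(seed)
    n <- 400
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    cov <- make_covariates(n, seed)
    y_bin <- rbinom(n, 1, plogis(-0.5 + 0.3 * g - 0.4 * (g == 1)))
    y_lin <- 0.3 * g - 0.4 * (g == 1) + rnorm(n)
    for (case in list(list(y = y_bin, m = "logistic"),
                      list(y = y_lin, m = "linear"))) {
      f1 <- fit_domdev(g, case$y, cov, model = case$m)
      f2 <- fit_genotypic(g, case$y, cov, model = case$m)
      expect_lt(abs(f1$loglik - f2$loglik), 1e-6)
      # coefficient mapping: AA-AB = -(beta + gamma), BB-AB = beta - gamma
      expect_equal(f2$effect_AA_vs_AB, -(f1$beta + f1$gamma),
                   tolerance = 1e-6)
      expect_equal(f2$effect_BB_vs_AB, f1$beta - f1$gamma, tolerance = 1e-6)
    }
  }
})

test_that("constraining gamma to zero reduces to the additive GWAS model", {
  set.seed(11)
  n <- 600
  g <- rbinom(n, 2, 0.3)
  cov <- make_covariates(n, 2)
  y <- rbinom(n, 1, plogis(-0.3 + 0.25 * g))
  fa <- fit_domdev(g, y, cov, model = "logistic", dominance = FALSE)
  X <- cbind(1, g, as.matrix(cov))
  ref <- suppressWarnings(glm.fit(X, y, family = binomial()))
  expect_equal(fa$beta, unname(ref$coefficients[2]), tolerance = 1e-8)
  expect_equal(fa$gamma, 0)
})

test_that("small-n ML fits match an exhaustive likelihood grid search", {
  # hand-built 30-individual dataset, no covariates
  g <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
         1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
         2L, 2L, 2L, 2L, 2L, 2L)
  y_bin <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 1L,
             1L, 1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L,
             1L, 1L, 0L, 1L, 1L, 1L)
  f <- fit_domdev(g, y_bin, model = "logistic")
  X <- cbind(1, g, as.integer(g == 1L))
  oracle <- grid_search_ml(loglik_logistic(X, y_bin),
                           lower = c(-6, -6, -6), upper = c(6, 6, 6))
  expect_equal(unname(f$beta), unname(oracle[2]), tolerance = 1e-3)
  expect_equal(unname(f$gamma), unname(oracle[3]), tolerance = 1e-3)

  set.seed(30)
  y_lin <- 0.5 * g + 0.8 * (g == 1) + rnorm(30)
  fl <- fit_domdev(g, y_lin, model = "linear")
  oracle_l <- grid_search_ml(negrss_linear(X, y_lin),
                             lower = c(-4, -4, -4), upper = c(4, 4, 4))
  expect_equal(unname(fl$beta), unname(oracle_l[2]), tolerance = 1e-3)
  expect_equal(unname(fl$gamma), unname(oracle_l[3]), tolerance = 1e-3)
})

test_that("complete dominance puts gamma at the additive effect size", {
  # under complete dominance the heterozygote sits at the homozygote value,
  # so the deviation term must absorb one full per-allele effect
  set.seed(12)
  n <- 60000
  g <- rbinom(n, 2, 0.3)
  y <- 0.4 * 2 * (g >= 1) + rnorm(n)  # het = minor hom = 0.8
  f <- fit_domdev(g, y, model = "linear")
  expect_gt(f$gamma, 0)
  expect_lt(abs(f$gamma - f$beta), 4 * sqrt(f$se_gamma^2 + f$se_beta^2))
  expect_lt(abs(f$beta - 0.4), 0.05)
})

test_that("genotypic contrasts isolate the matching homozygote", {
  set.seed(13)
  n <- 40000
  g <- rbinom(n, 2, 0.3)
  # complete recessive: only minor homozygotes shift, so AB ~ AA
  y <- 0.5 * (g == 2) + rnorm(n)
  fg <- fit_genotypic(g, y, model = "linear")
  expect_gt(fg$p_AB_AA, 0.05)
  expect_lt(fg$p_AB_BB, 0.05)
  # equal AA and AB class means -> near-null contrast
  y2 <- rnorm(n)
  y2[g == 2] <- y2[g == 2] + 1
  fg2 <- fit_genotypic(g, y2, model = "linear")
  expect_gt(fg2$p_AB_AA, 0.05)
})

test_that("missing genotypes are dropped per variant and classes are required", {
  set.seed(14)
  g <- c(rbinom(300, 2, 0.4), NA, NA)
  y <- rnorm(302)
  f <- fit_domdev(g, y, model = "linear")
  expect_equal(f$n_used, 300)
  expect_error(fit_domdev(rep(1L, 50), rnorm(50), model = "linear"),
               "genotype classes")
  f2 <- fit_domdev(c(rep(0L, 30), rep(1L, 30)), rnorm(60), model = "linear")
  expect_false(f2$converged)
  expect_equal(f2$reason, "missing_genotype_class")
  fg <- fit_genotypic(c(rep(0L, 30), rep(1L, 30)), rnorm(60),
                      model = "linear")
  expect_false(fg$converged)
})

test_that("an orthogonal covariate leaves the genetic coefficients alone", {
  set.seed(15)
  n <- 5000
  g <- rbinom(n, 2, 0.25)
  y <- 0.2 * g + rnorm(n)
  junk <- data.frame(noise = rnorm(n))
  f0 <- fit_domdev(g, y, model = "linear")
  f1 <- fit_domdev(g, y, junk, model = "linear")
  expect_lt(abs(f0$beta - f1$beta), 3 * f0$se_beta * 0.05)
  expect_lt(abs(f0$gamma - f1$gamma), 3 * f0$se_gamma * 0.05)
})

test_that("assoc_scan tabulates per-variant fits in association-table layout", {
  set.seed(16)
  p <- default_panel(6, seed = 1)
  G <- simulate_genotypes(p, 800, seed = 2)
  y <- simulate_phenotype(G, p, 0.05, noise_seed = 3)
  tab <- assoc_scan(G, y, model = "linear")
  expect_equal(nrow(tab), 6)
  expect_true(all(c("variant_id", "maf", "beta", "se_beta", "p_beta",
                    "gamma", "se_gamma", "p_gamma", "p_AB_AA", "p_AB_BB")
                  %in% names(tab)))
  one <- fit_domdev(G[, 3], y, model = "linear")
  expect_equal(tab$beta[3], one$beta)
  expect_equal(tab$p_gamma[3], one$p_gamma)
})
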