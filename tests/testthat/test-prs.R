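test_that("compute_prs is the weighted coding sum", {
  G <- rbind(c(1L, 2L), c(0L, 1L), c(2L, 0L))
  colnames(G) <- c("v1", "v2")
  w0 <- data.frame(variant_id = c("v1", "v2"), beta_weight = 0,
                   gamma_weight = 0)
  expect_equal(compute_prs(w0, G), c(0, 0, 0))
  w <- data.frame(variant_id = c("v1", "v2"), beta_weight = c(0.1, -0.2),
                  gamma_weight = c(0.05, 0))
  # individual 1: 0.1*1 + 0.05*1 + (-0.2)*2 = -0.25
  expect_equal(compute_prs(w, G)[1], -0.25)
  # gamma all zero reduces exactly to the additive score
  wg0 <- w; wg0$gamma_weight <- 0
  expect_equal(compute_prs(wg0, G),
               as.vector(G %*% wg0$beta_weight), tolerance = 1e-12)
  # orientation / panel mismatch is rejected with the variant named
  wbad <- data.frame(variant_id = "v9", beta_weight = 1, gamma_weight = 0)
  expect_error(compute_prs(wbad, G), "v9")
})

test_that("missing genotypes contribute the variant's mean coding values", {
  G <- cbind(v1 = c(0L, 1L, 2L, NA))
  w <- data.frame(variant_id = "v1", beta_weight = 1, gamma_weight = 10)
  s <- compute_prs(w, G)
  expect_equal(s[4], mean(c(0, 1, 2)) + 10 * mean(c(0, 1, 0)))
})

test_that("build_prs_weights implements the three score definitions", {
  add <- data.frame(variant_id = paste0("v", 1:5),
                    beta = c(0.1, -0.2, 0.3, 0, 0.05))
  joint <- data.frame(variant_id = paste0("v", 1:5),
                      beta = c(0.12, -0.18, 0.25, 0.02, 0.04),
                      gamma = c(0.2, -0.1, 0.05, 0.01, -0.02))
  w1 <- build_prs_weights(add, mode = "prs1")
  expect_true(all(w1$gamma_weight == 0))
  expect_equal(attr(w1, "source"), "additive_fit")
  w2 <- build_prs_weights(add, joint, mode = "prs2")
  expect_equal(w2$beta_weight, joint$beta)
  expect_equal(w2$gamma_weight, joint$gamma)
  sel <- c("v1", "v3")
  w3 <- build_prs_weights(add, joint, mode = "prs3", selected = sel)
  expect_equal(attr(w3, "source"), "mixed")
  in_sel <- w3$variant_id %in% sel
  expect_equal(w3$gamma_weight[!in_sel], rep(0, 3))
  expect_equal(w3$beta_weight[!in_sel], add$beta[!in_sel])
  expect_equal(w3$beta_weight[in_sel], joint$beta[c(1, 3)])
  # empty selection degenerates to the conventional score
  w3e <- build_prs_weights(add, joint, mode = "prs3")
  expect_equal(w3e$beta_weight, w1$beta_weight)
  expect_equal(w3e$gamma_weight, w1$gamma_weight)
  expect_error(build_prs_weights(add, joint, mode = "prs3",
                                 selected = "v99"), "v99")
})

test_that("adjusted R-squared matches the textbook formula on a hand example", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.2, 1.9, 3.2, 3.8, 5.1)
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  expect_equal(domdev:::adj_r2(cbind(1, x), y),
               1 - (1 - r2) * (5 - 1) / (5 - 1 - 1), tolerance = 1e-12)
  expect_equal(domdev:::adj_r2(cbind(1, x), y), summary(fit)$adj.r.squared,
               tolerance = 1e-12)
})

test_that("evaluate_prs recovers a planned incremental variance fraction", {
  set.seed(41)
  n <- 50000
  age <- runif(n, 40, 69); gender <- rbinom(n, 1, 0.5)
  score <- rnorm(n)
  # outcome built so the score explains ~6% of variance beyond age+gender
  y <- 0.01 * age - 0.1 * gender + sqrt(0.06) * score +
    sqrt(1 - 0.06) * rnorm(n)
  ev <- evaluate_prs(score, y, age, gender, n_bootstrap = 60, seed = 2)
  expect_lt(abs(ev$r2_delta - 0.06), 0.004)
  expect_true(ev$ci_low <= ev$r2_delta && ev$r2_delta <= ev$ci_high)
  expect_equal(ev$n_bootstrap, 60)

  # null score: no incremental variance
  ev0 <- evaluate_prs(rnorm(n), y, age, gender, n_bootstrap = 30, seed = 3)
  expect_lt(abs(ev0$r2_delta), 5e-4)

  # affine invariance of the incremental adjusted R-squared
  ev_shift <- evaluate_prs(score + 100, y, age, gender, n_bootstrap = 30,
                           seed = 4)
  ev_base <- evaluate_prs(score, y, age, gender, n_bootstrap = 30, seed = 4)
  expect_equal(ev_shift$r2_delta, ev_base$r2_delta, tolerance = 1e-10)
  # determinism given the seed
  expect_identical(ev_shift$ci_low,
                   evaluate_prs(score + 100, y, age, gender,
                                n_bootstrap = 30, seed = 4)$ci_low)
})

test_that("the dominance-aware score never fits worse in-sample", {
  set.seed(43)
  pair <- simulate_cohort_pair(cohort_config(
    n_discovery = 5000, n_replication = 2000,
    panel = default_panel(8, mode = "dominant", seed = 6),
    genetic_r2 = 0.08, seed = 13))
  d <- pair$discovery
  y <- as.integer(d$phenotypes$myopia_true)
  C <- as.matrix(d$covariates)
  for (j in 1:3) {
    f_add <- fit_domdev(d$genotypes[, j], y, C, model = "logistic",
                        dominance = FALSE)
    f_joint <- fit_domdev(d$genotypes[, j], y, C, model = "logistic")
    expect_gte(f_joint$loglik, f_add$loglik - 1e-8)
  }
})

test_that("weights file round-trips", {
  add <- data.frame(variant_id = c("a", "b"), beta = c(0.1, 0.2))
  joint <- data.frame(variant_id = c("a", "b"), beta = c(0.15, 0.18),
                      gamma = c(0.3, -0.2))
  w <- build_prs_weights(add, joint, mode = "prs2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prs_weights(w, path)
  w2 <- read_prs_weights(path)
  expect_equal(w2$beta_weight, w$beta_weight)
  expect_equal(w2$gamma_weight, w$gamma_weight)
  expect_equal(attr(w2, "source"), "domdev_fit")
})
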