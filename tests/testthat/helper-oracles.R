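# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own fitting/selection code paths.

# Exhaustive likelihood maximization by iterative grid refinement: evaluates
# ll on a full k^d grid, re-centres on the best point and shrinks the span,
# repeated until the resolution is well below the comparison tolerance.
grid_search_ml <- function(ll, lower, upper, k = 13, iters = 7) {
  d <- length(lower)
  for (it in seq_len(iters)) {
    axes <- lapply(seq_len(d), function(j) seq(lower[j], upper[j],
                                               length.out = k))
    grid <- as.matrix(do.call(expand.grid, axes))
    vals <- apply(grid, 1, ll)
    best <- grid[which.max(vals), ]
    span <- (upper - lower) / (k - 1)
    lower <- best - span
    upper <- best + span
  }
  best
}

loglik_logistic <- function(X, y) {
  function(theta) {
    eta <- as.vector(X %*% theta)
    sum(y * eta - log1p(exp(eta)))
  }
}

# linear model: sigma profiles out, maximizing the likelihood = minimizing RSS
negrss_linear <- function(X, y) {
  function(theta) -sum((y - as.vector(X %*% theta))^2)
}

# Additive/dominance variance partition by exhaustive 3-genotype enumeration:
# weighted least-squares fit of the genotypic values on allele count.
enumeration_additive_share <- function(values, maf) {
  w <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  g <- 0:2
  mg <- sum(w * g); mv <- sum(w * values)
  cov_gv <- sum(w * (g - mg) * (values - mv))
  var_g <- sum(w * (g - mg)^2)
  var_v <- sum(w * (values - mv)^2)
  (cov_gv^2 / var_g) / var_v
}

# Brute-force dual ROC threshold search over every candidate probability cut.
roc_thresholds_bruteforce <- function(p, y, spec_target = 0.9,
                                      sens_target = 0.9) {
  cuts <- sort(unique(p))
  spec <- vapply(cuts, function(c) mean(p[y == 0] < c), numeric(1))
  sens <- vapply(cuts, function(c) mean(p[y == 1] >= c), numeric(1))
  t_spec <- min(cuts[spec >= spec_target])
  t_sens <- max(cuts[sens >= sens_target])
  if (t_spec < t_sens) t_sens <- t_spec
  list(spec90 = t_spec, sens90 = t_sens)
}

# Exact HWE chi-square goodness of fit for one genotype column.
hwe_chisq_p <- function(g, maf) {
  n <- length(g)
  obs <- tabulate(g + 1L, 3L)
  exp <- n * c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  stat <- sum((obs - exp)^2 / exp)
  stats::pchisq(stat, df = 2, lower.tail = FALSE)
}

# Small helper: a deterministic covariate block for association tests.
make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = runif(n, 40, 69), gender = rbinom(n, 1, 0.5),
             pc1 = rnorm(n), pc2 = rnorm(n))
}
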