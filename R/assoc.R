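#' Two-sided Wald p-value
#'
#' Normal-approximation `p = 2 * pnorm(-|coef / se|)`, the test-statistic
#' convention used for every reported p-value in the pipeline.
#'
#' @param coefficient estimate.
#' @param se standard error (> 0).
#' @return p-value in `(0, 1]`.
#' @export
wald_p <- function(coefficient, se) {
  if (any(!is.finite(se) | se <= 0)) stop("se must be positive and finite")
  2 * stats::pnorm(-abs(coefficient / se))
}

# Shared single-variant fitting engine. Builds [1 | codings | covariates],
# drops rows with a missing genotype (complete-case per variant), fits by
# least squares or IRLS (epsilon 1e-8, maxit 100), and returns coefficients,
# Wald SEs from the (weighted) information matrix, and the log-likelihood.
fit_engine <- function(X, y, model) {
  n <- nrow(X); p <- ncol(X)
  if (model == "logistic") {
    fit <- suppressWarnings(stats::glm.fit(
      X, y, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    mu <- fit$fitted.values
    separated <- any(mu < 1e-10 | mu > 1 - 1e-10)
    converged <- fit$converged && !separated
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    reason <- if (separated) "separation" else if (!fit$converged)
      "no_convergence" else NA_character_
  } else {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - p)
    XtX <- crossprod(X)
    vc <- tryCatch(chol2inv(chol(XtX)) * sigma2, error = function(e) NULL)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    converged <- is.finite(rss) && fit$rank == p
    reason <- if (!converged) "rank_deficient" else NA_character_
  }
  if (is.null(vc)) {
    converged <- FALSE
    reason <- "singular_information"
    vc <- matrix(NA_real_, p, p)
  }
  list(coef = fit$coefficients, se = sqrt(pmax(diag(vc), 0)),
       loglik = ll, converged = converged, reason = reason,
       fitted = fit$fitted.values)
}

prepare_design <- function(genotype, outcome, covariates, extra_cols) {
  stopifnot(all(is.na(genotype) | genotype %in% 0:2))
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- !is.na(genotype) & !is.na(outcome)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  g <- genotype[keep]
  y <- outcome[keep]
  X <- cbind(`(Intercept)` = 1, extra_cols(g))
  if (!is.null(C)) X <- cbind(X, C[keep, , drop = FALSE])
  list(X = X, y = y, g = g)
}

#' Fit the dominance-deviation association model for one variant
#'
#' Jointly regresses the outcome on the minor-allele count (`snp_add`), the
#' heterozygosity indicator (`snp_domdev`) and the covariate block. For a
#' binary outcome (AOSW-inferred myopia) the model is logistic; for a
#' continuous outcome (refractive error) it is linear. The dominance
#' deviation coefficient `gamma` measures the heterozygote's departure from
#' the additive expectation; its two-sided Wald p-value is the screening
#' statistic. Rows with a missing genotype are dropped for this variant
#' only. With `dominance = FALSE` the `snp_domdev` term is omitted,
#' reducing to the standard additive GWAS model (used for conventional PRS
#' weights).
#'
#' @param genotype integer vector in `{0, 1, 2, NA}`.
#' @param outcome binary (0/1 or logical) or continuous vector.
#' @param covariates optional data.frame/matrix of adjustment covariates
#'   (age, age squared, gender, array, principal components); no missing
#'   values expected.
#' @param model `"auto"` (binary outcome -> logistic), `"logistic"` or
#'   `"linear"`.
#' @param dominance include the dominance-deviation term (default TRUE).
#' @param variant_id label carried into the result.
#' @return object of class `"domdev_fit"`: `beta`, `gamma`, `se_beta`,
#'   `se_gamma`, `p_beta`, `p_gamma`, `n_used`, `model`, `converged` (plus a
#'   `reason` when not), and `loglik`.
#' @export
fit_domdev <- function(genotype, outcome, covariates = NULL,
                       model = c("auto", "logistic", "linear"),
                       dominance = TRUE, variant_id = NA_character_) {
  model <- match.arg(model)
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (is.factor(outcome)) stop("factor outcomes are not supported; supply 0/1")
  if (model == "auto") {
    model <- if (all(outcome %in% c(0, 1, NA))) "logistic" else "linear"
  }
  if (stats::var(outcome, na.rm = TRUE) == 0) stop("degenerate outcome")
  cols <- if (dominance) {
    function(g) cbind(snp_add = g, snp_domdev = as.integer(g == 1L))
  } else {
    function(g) cbind(snp_add = g)
  }
  d <- prepare_design(genotype, outcome, covariates, cols)
  if (length(unique(d$g)) < 2) {
    stop("fewer than 2 genotype classes present for variant ", variant_id)
  }
  if (dominance && length(unique(d$g)) < 3) {
    # with two classes add + domdev are collinear; flag rather than fit
    return(structure(list(variant_id = variant_id, model = model,
                          beta = NA_real_, gamma = NA_real_,
                          se_beta = NA_real_, se_gamma = NA_real_,
                          p_beta = NA_real_, p_gamma = NA_real_,
                          n_used = length(d$y), loglik = NA_real_,
                          converged = FALSE, reason = "missing_genotype_class"),
                     class = "domdev_fit"))
  }
  f <- fit_engine(d$X, d$y, model)
  b <- f$coef["snp_add"]; sb <- f$se[match("snp_add", colnames(d$X))]
  if (dominance) {
    gma <- f$coef["snp_domdev"]
    sg <- f$se[match("snp_domdev", colnames(d$X))]
  } else {
    gma <- 0; sg <- NA_real_
  }
  structure(list(
    variant_id = variant_id, model = model,
    beta = unname(b), gamma = unname(gma),
    se_beta = unname(sb), se_gamma = unname(sg),
    p_beta = if (f$converged) unname(wald_p(b, sb)) else NA_real_,
    p_gamma = if (dominance && f$converged) unname(wald_p(gma, sg))
              else NA_real_,
    n_used = length(d$y), loglik = f$loglik,
    converged = f$converged, reason = f$reason), class = "domdev_fit")
}

#' Fit the genotypic (heterozygote-referenced) model for one variant
#'
#' Regresses the outcome on the genotype as a categorical factor with the
#' heterozygote (AB) as reference, with the same covariate adjustment as
#' [fit_domdev()]. The two contrasts — AA vs AB and BB vs AB — operationally
#' define "consistent with complete dominance or recessive action": a
#' variant qualifies when either contrast has p > 0.05 (the heterozygote is
#' statistically indistinguishable from one homozygote). This model is a
#' reparameterization of the dominance-deviation model; both are saturated
#' in genotype and share their maximized likelihood.
#'
#' @inheritParams fit_domdev
#' @return object of class `"genotypic_fit"` with `effect_AA_vs_AB`,
#'   `effect_BB_vs_AB`, their SEs, `p_AB_AA`, `p_AB_BB`, `n_used`,
#'   `converged`, `loglik`.
#' @export
fit_genotypic <- function(genotype, outcome, covariates = NULL,
                          model = c("auto", "logistic", "linear"),
                          variant_id = NA_character_) {
  model <- match.arg(model)
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (model == "auto") {
    model <- if (all(outcome %in% c(0, 1, NA))) "logistic" else "linear"
  }
  cols <- function(g) cbind(geno_AA = as.integer(g == 0L),
                            geno_BB = as.integer(g == 2L))
  d <- prepare_design(genotype, outcome, covariates, cols)
  if (length(unique(d$g)) < 3) {
    return(structure(list(variant_id = variant_id, model = model,
                          effect_AA_vs_AB = NA_real_,
                          effect_BB_vs_AB = NA_real_,
                          se_AA_vs_AB = NA_real_, se_BB_vs_AB = NA_real_,
                          p_AB_AA = NA_real_, p_AB_BB = NA_real_,
                          n_used = length(d$y), loglik = NA_real_,
                          converged = FALSE, reason = "missing_genotype_class"),
                     class = "genotypic_fit"))
  }
  f <- fit_engine(d$X, d$y, model)
  i0 <- match("geno_AA", colnames(d$X)); i2 <- match("geno_BB", colnames(d$X))
  structure(list(
    variant_id = variant_id, model = model,
    effect_AA_vs_AB = unname(f$coef["geno_AA"]),
    effect_BB_vs_AB = unname(f$coef["geno_BB"]),
    se_AA_vs_AB = f$se[i0], se_BB_vs_AB = f$se[i2],
    p_AB_AA = if (f$converged) unname(wald_p(f$coef["geno_AA"], f$se[i0]))
              else NA_real_,
    p_AB_BB = if (f$converged) unname(wald_p(f$coef["geno_BB"], f$se[i2]))
              else NA_real_,
    n_used = length(d$y), loglik = f$loglik,
    converged = f$converged, reason = f$reason), class = "genotypic_fit")
}

#' @export
print.domdev_fit <- function(x, ...) {
  cat(sprintf(
    "<domdev_fit %s (%s)> beta = %.4f (SE %.4f, p = %.3g); gamma = %.4f (SE %.4f, p = %.3g); n = %d%s\n",
    x$variant_id, x$model, x$beta, x$se_beta, x$p_beta, x$gamma, x$se_gamma,
    x$p_gamma, x$n_used,
    if (isTRUE(x$converged)) "" else paste0(" [", x$reason, "]")))
  invisible(x)
}

#' @export
print.genotypic_fit <- function(x, ...) {
  cat(sprintf(
    "<genotypic_fit %s (%s)> AA-AB = %.4f (p = %.3g); BB-AB = %.4f (p = %.3g); n = %d%s\n",
    x$variant_id, x$model, x$effect_AA_vs_AB, x$p_AB_AA, x$effect_BB_vs_AB,
    x$p_AB_BB, x$n_used,
    if (isTRUE(x$converged)) "" else paste0(" [", x$reason, "]")))
  invisible(x)
}

#' Per-variant association scan across a genotype matrix
#'
#' Applies [fit_domdev()] (and optionally [fit_genotypic()]) to every
#' column, returning a table mirroring the standard association-results
#' layout: variant, MAF, additive beta/SE/p, dominance-deviation
#' beta/SE/p, and (when requested) the two heterozygote-referenced contrast
#' p-values.
#'
#' @param genotypes individuals x variants matrix.
#' @param outcome,covariates,model passed to the per-variant fitters.
#' @param genotypic also fit the genotypic model (default TRUE).
#' @param dominance passed to [fit_domdev()]; `FALSE` gives an
#'   additive-only scan.
#' @return data.frame, one row per variant.
#' @export
assoc_scan <- function(genotypes, outcome, covariates = NULL,
                       model = "auto", genotypic = TRUE, dominance = TRUE) {
  ids <- colnames(genotypes) %||% as.character(seq_len(ncol(genotypes)))
  rows <- lapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    fd <- fit_domdev(g, outcome, covariates, model, dominance = dominance,
                     variant_id = ids[j])
    out <- data.frame(
      variant_id = ids[j],
      maf = as.numeric(minor_allele_frequency(g)),
      beta = fd$beta, se_beta = fd$se_beta, p_beta = fd$p_beta,
      gamma = fd$gamma, se_gamma = fd$se_gamma, p_gamma = fd$p_gamma,
      n_used = fd$n_used, converged = fd$converged,
      stringsAsFactors = FALSE)
    if (genotypic) {
      fg <- fit_genotypic(g, outcome, covariates, model, variant_id = ids[j])
      out$p_AB_AA <- fg$p_AB_AA
      out$p_AB_BB <- fg$p_AB_BB
      out$genotypic_converged <- fg$converged
    }
    out
  })
  do.call(rbind, rows)
}
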