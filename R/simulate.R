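#' Simulate hard-call genotypes under Hardy-Weinberg equilibrium
#'
#' Each genotype is an independent draw from Binomial(2, MAF) — variants are
#' unlinked, so HWE class proportions (1-q)^2, 2q(1-q), q^2 hold at every
#' variant.
#'
#' @param panel a `variant_panel`.
#' @param n number of individuals (>= 1).
#' @param seed integer seed; the matrix is deterministic given it.
#' @return integer matrix `n x nrow(panel)` of minor-allele counts, with
#'   `colnames` the variant ids.
#' @export
simulate_genotypes <- function(panel, n, seed = NULL) {
  stopifnot(n >= 1)
  bad <- !is.finite(panel$maf) | panel$maf <= 0 | panel$maf > 0.5
  if (any(bad)) {
    stop("invalid MAF for variant(s): ",
         paste(panel$variant_id[bad], collapse = ", "))
  }
  local_rng(seed)
  # compiled inverse-CDF Binomial(2, maf) draw on R's RNG stream
  G <- .hwe_draw(as.integer(n), panel$maf)$G
  storage.mode(G) <- "integer"
  colnames(G) <- panel$variant_id
  G
}

#' Simulate a quantitative phenotype from genotypes
#'
#' The genetic component is the sum over variants of the genotypic value
#' `beta * g + gamma * (g == 1)`, rescaled so its Hardy-Weinberg population
#' variance equals `target_r2` of the total phenotype variance (fixed at 1);
#' Gaussian noise supplies the remaining `1 - target_r2`.
#'
#' @param genotypes matrix from [simulate_genotypes()] (columns must match
#'   the panel order).
#' @param panel a `variant_panel`.
#' @param target_r2 fraction of variance explained by the variants jointly,
#'   in `[0, 1)`.
#' @param noise_seed optional seed for the noise draw.
#' @return numeric phenotype vector with attribute `"scale"` (the multiplier
#'   applied to the raw genetic component).
#' @export
simulate_phenotype <- function(genotypes, panel, target_r2,
                               noise_seed = NULL) {
  if (!is.finite(target_r2) || target_r2 < 0 || target_r2 >= 1) {
    stop("target_r2 must lie in [0, 1)")
  }
  z <- genetic_component(genotypes, panel)
  vg <- panel_genetic_variance(panel)
  if (target_r2 > 0 && vg <= 0) {
    stop("all-zero genetic effects cannot be rescaled to target_r2 > 0")
  }
  sc <- if (target_r2 > 0) sqrt(target_r2 / vg) else 0
  local_rng(noise_seed)
  y <- sc * z + stats::rnorm(length(z), sd = sqrt(1 - target_r2))
  attr(y, "scale") <- sc
  y
}

#' @rdname simulate_phenotype
#' @export
genetic_component <- function(genotypes, panel) {
  stopifnot(ncol(genotypes) == nrow(panel))
  as.vector(genotypes %*% panel$beta_true +
              (genotypes == 1L) %*% panel$gamma_true)
}

#' Configuration for the synthetic discovery/replication cohort pair
#'
#' Defaults emulate the biobank design the pipeline targets: a discovery
#' sample of 228,423 individuals whose myopia status must be inferred from
#' age of onset of spectacle wear (AOSW), and a replication sample of 73,577
#' individuals with autorefraction-measured refractive error. Refractive
#' error is drawn with a UK-population-like mean of -0.25 D and SD 2.7 D;
#' the panel variants jointly explain `genetic_r2` (default 6%) of its
#' variance. AOSW follows a monotone stochastic link (earlier onset for more
#' myopic eyes): wearers get `aosw_intercept + aosw_slope * RE + noise`,
#' clamped to `[5, 60]` years, and the probability of ever wearing
#' spectacles increases with myopia severity.
#'
#' @param n_discovery,n_replication sample sizes.
#' @param panel variant panel shared by both cohorts.
#' @param genetic_r2 variance fraction of refractive error explained by the
#'   panel.
#' @param myopia_cut dioptre threshold defining true myopia (mean spherical
#'   equivalent at or below it).
#' @param re_mean,re_sd marginal refractive-error mean/SD in dioptres.
#' @param aosw_intercept,aosw_slope,aosw_sd AOSW link (years, years per
#'   dioptre, residual SD in years).
#' @param wear_intercept,wear_slope logistic model for ever wearing
#'   spectacles as a function of refractive error.
#' @param age_effect,gender_effect covariate effects on refractive error
#'   (dioptres per year from age 55; dioptres for gender = 1).
#' @param seed master seed; the cohort pair is fully deterministic given the
#'   config.
#' @return a list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_discovery = 228423, n_replication = 73577,
                          panel = default_panel(), genetic_r2 = 0.06,
                          myopia_cut = -0.75, re_mean = -0.25, re_sd = 2.7,
                          aosw_intercept = 16, aosw_slope = 2.2,
                          aosw_sd = 5, wear_intercept = 0.4,
                          wear_slope = -0.45, age_effect = -0.01,
                          gender_effect = -0.1, seed = 1L) {
  cfg <- list(n_discovery = n_discovery, n_replication = n_replication,
              panel = panel, genetic_r2 = genetic_r2,
              myopia_cut = myopia_cut, re_mean = re_mean, re_sd = re_sd,
              aosw_intercept = aosw_intercept, aosw_slope = aosw_slope,
              aosw_sd = aosw_sd, wear_intercept = wear_intercept,
              wear_slope = wear_slope, age_effect = age_effect,
              gender_effect = gender_effect, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

simulate_one_cohort <- function(cfg, n, id_prefix, seed) {
  local_rng(seed)
  panel <- cfg$panel
  ids <- sprintf("%s%06d", id_prefix, seq_len(n))
  G <- simulate_genotypes(panel, n, seed = NULL)
  rownames(G) <- ids

  age <- stats::runif(n, 40, 69)
  gender <- stats::rbinom(n, 1L, 0.5)
  array <- stats::rbinom(n, 1L, 0.1)  # stand-in genotyping-array indicator
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))

  vg <- panel_genetic_variance(panel)
  sc <- if (cfg$genetic_r2 > 0) {
    if (vg <= 0) stop("panel has no genetic variance to scale")
    cfg$re_sd * sqrt(cfg$genetic_r2 / vg)
  } else 0
  z <- genetic_component(G, panel)
  noise_sd <- cfg$re_sd * sqrt(max(0, 1 - cfg$genetic_r2))
  re <- cfg$re_mean + sc * z +
    cfg$age_effect * (age - 55) + cfg$gender_effect * gender +
    stats::rnorm(n, sd = noise_sd)

  p_wear <- stats::plogis(cfg$wear_intercept + cfg$wear_slope * re)
  wears <- stats::runif(n) < p_wear
  aosw <- rep(NA_real_, n)
  aosw[wears] <- pmin(60, pmax(5, round(
    cfg$aosw_intercept + cfg$aosw_slope * re[wears] +
      stats::rnorm(sum(wears), sd = cfg$aosw_sd))))

  covariates <- data.frame(age = age, age_squared = (age - mean(age))^2,
                           gender = gender, array = array, pcs)
  phen <- data.frame(individual_id = ids, refractive_error = re,
                     aosw = aosw, never_wearer = !wears,
                     myopia_true = re <= cfg$myopia_cut,
                     stringsAsFactors = FALSE)
  structure(list(n = n, genotypes = G, phenotypes = phen,
                 covariates = covariates, panel = panel, seed = seed),
            class = "cohort")
}

#' Simulate a discovery/replication cohort pair
#'
#' Generates two disjoint cohorts from a shared variant panel. The
#' replication-style cohort carries measured refractive error (and AOSW where
#' available, which is what the AOSW classifier is trained on); the
#' discovery-style cohort masks refractive error, leaving AOSW as the only
#' phenotype — its myopia status must be inferred downstream. True myopia
#' labels are retained in both for validation.
#'
#' @param config a [cohort_config()].
#' @return list with elements `discovery` and `replication`, both of class
#'   `"cohort"`, plus the `config`.
#' @export
simulate_cohort_pair <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  disc <- simulate_one_cohort(config, config$n_discovery, "D",
                              derive_seed(config$seed, 1L))
  repl <- simulate_one_cohort(config, config$n_replication, "R",
                              derive_seed(config$seed, 2L))
  if (any(disc$phenotypes$individual_id %in%
            repl$phenotypes$individual_id)) {
    stop("discovery and replication individual ids overlap")
  }
  disc$phenotypes$refractive_error <- NA_real_  # AOSW-only stage
  list(discovery = disc, replication = repl, config = config)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> n = %d, %d variants; phenotypes: %s\n", x$n,
              ncol(x$genotypes),
              paste(names(x$phenotypes)[-1], collapse = ", ")))
  invisible(x)
}

#' Write a cohort to tab-separated files
#'
#' Emits `<prefix>_phenotypes.tsv` (phenotypes + covariates) and
#' `<prefix>_genotypes.tsv` (individual by variant hard calls); the
#' generating seed is recorded in a `# seed:` header comment of the
#' phenotype file.
#'
#' @param cohort a `"cohort"`.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  ppath <- paste0(prefix, "_phenotypes.tsv")
  gpath <- paste0(prefix, "_genotypes.tsv")
  con <- file(ppath, "w")
  writeLines(sprintf("# seed: %s", cohort$seed), con)
  utils::write.table(cbind(cohort$phenotypes, cohort$covariates), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  write_genotypes(cohort$genotypes, gpath)
  invisible(c(ppath, gpath))
}
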