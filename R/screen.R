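#' Bonferroni significance threshold
#'
#' `alpha / m` for `m` tests — e.g. 0.05/146 = 3.42e-4 for the full panel in
#' discovery and 0.05/8 = 6.25e-3 for eight forwarded variants in
#' replication.
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (>= 1).
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.finite(m) || m < 1) stop("m must be a positive count")
  stopifnot(alpha > 0, alpha < 1)
  alpha / m
}

#' Replications expected by chance
#'
#' Under the null, each of `n_forwarded` variants replicates at nominal
#' level `alpha` with probability `alpha`, so `n_forwarded * alpha` are
#' expected by chance (0.4 out of 8 at alpha = 0.05).
#'
#' @param n_forwarded count of variants tested in replication (>= 0).
#' @param alpha nominal level.
#' @return expected count.
#' @export
expected_by_chance <- function(n_forwarded, alpha = 0.05) {
  stopifnot(n_forwarded >= 0)
  n_forwarded * alpha
}

#' Run the two-stage dominance screen
#'
#' Stage 1 (discovery, binary myopia outcome, logistic models): every panel
#' variant gets a dominance-deviation fit and a genotypic
#' (heterozygote-referenced) fit with full covariate adjustment. A variant
#' shows *nominal non-additivity* when the dominance-deviation p-value is
#' below `alpha`, and is *consistent with complete dominance or recessive
#' action* when either heterozygote contrast (AA vs AB, BB vs AB) has
#' p > `alpha`. Variants passing both criteria are forwarded.
#'
#' Stage 2 (replication, continuous refractive error, linear models): each
#' forwarded variant gets a dominance-deviation fit; replication is called
#' at the Bonferroni threshold `alpha / n_forwarded` (and, separately, at
#' the nominal level). The discovery Bonferroni threshold `alpha / m` is
#' reported descriptively only — forwarding is nominal, as in the original
#' design. Non-converged or class-deficient fits are flagged and excluded
#' from forwarding; a forwarded variant lacking all three genotype classes
#' in replication is reported untestable rather than failed.
#'
#' @param discovery a `"cohort"` (or list with `genotypes`, `covariates`).
#' @param replication a `"cohort"` carrying `refractive_error`.
#' @param myopia_labels discovery myopia status: a factor from [classify()]
#'   (unclassified individuals are excluded) or a logical/0-1 vector. If
#'   `NULL`, `discovery$phenotypes$myopia_true` is used.
#' @param alpha nominal level (default 0.05).
#' @param variants optional variant-id subset.
#' @return object of class `"screen_result"`: `results`, one row per variant
#'   with fits and stage flags, and `summary`, the stage counts with the
#'   expected-by-chance number and both Bonferroni thresholds.
#' @export
run_screen <- function(discovery, replication, myopia_labels = NULL,
                       alpha = 0.05, variants = NULL) {
  if (is.null(myopia_labels)) myopia_labels <- discovery$phenotypes$myopia_true
  if (is.factor(myopia_labels)) {
    keep <- myopia_labels %in% c("myopic", "non_myopic")
    y_disc <- as.integer(myopia_labels == "myopic")
  } else {
    y_disc <- as.integer(myopia_labels)
    keep <- !is.na(y_disc)
  }
  Gd <- discovery$genotypes; Cd <- as.matrix(discovery$covariates)
  Gr <- replication$genotypes; Cr <- as.matrix(replication$covariates)
  if (!identical(colnames(Gd), colnames(Gr))) {
    stop("discovery and replication genotypes must share an oriented panel")
  }
  ids <- variants %||% colnames(Gd)
  Gd <- Gd[keep, ids, drop = FALSE]
  yd <- y_disc[keep]; Cd <- Cd[keep, , drop = FALSE]
  yr <- replication$phenotypes$refractive_error

  rows <- lapply(ids, function(v) {
    fd <- fit_domdev(Gd[, v], yd, Cd, model = "logistic", variant_id = v)
    fg <- fit_genotypic(Gd[, v], yd, Cd, model = "logistic", variant_id = v)
    nominal <- isTRUE(fd$converged) && !is.na(fd$p_gamma) &&
      fd$p_gamma < alpha
    consistent <- isTRUE(fg$converged) &&
      ((!is.na(fg$p_AB_AA) && fg$p_AB_AA > alpha) ||
         (!is.na(fg$p_AB_BB) && fg$p_AB_BB > alpha))
    forwarded <- nominal && consistent
    data.frame(
      variant_id = v, maf = as.numeric(minor_allele_frequency(Gd[, v])),
      disc_beta = fd$beta, disc_se_beta = fd$se_beta, disc_p_beta = fd$p_beta,
      disc_gamma = fd$gamma, disc_se_gamma = fd$se_gamma,
      disc_p_gamma = fd$p_gamma,
      p_AB_AA = fg$p_AB_AA, p_AB_BB = fg$p_AB_BB,
      nominal_nonadditive = nominal, full_dom_or_rec = consistent,
      forwarded = forwarded, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)

  res$repl_beta <- res$repl_se_beta <- res$repl_p_beta <- NA_real_
  res$repl_gamma <- res$repl_se_gamma <- res$repl_p_gamma <- NA_real_
  res$repl_untestable <- FALSE
  res$replicated_nominal <- res$replicated_bonferroni <- FALSE
  fwd <- which(res$forwarded)
  bon_repl <- if (length(fwd)) bonferroni_threshold(alpha, length(fwd))
              else NA_real_
  for (i in fwd) {
    v <- res$variant_id[i]
    fr <- fit_domdev(Gr[, v], yr, Cr, model = "linear", variant_id = v)
    res$repl_beta[i] <- fr$beta; res$repl_se_beta[i] <- fr$se_beta
    res$repl_p_beta[i] <- fr$p_beta
    res$repl_gamma[i] <- fr$gamma; res$repl_se_gamma[i] <- fr$se_gamma
    res$repl_p_gamma[i] <- fr$p_gamma
    if (!isTRUE(fr$converged)) {
      res$repl_untestable[i] <- TRUE
    } else {
      res$replicated_nominal[i] <- fr$p_gamma < alpha
      res$replicated_bonferroni[i] <- fr$p_gamma < bon_repl
    }
  }
  summary <- list(
    n_variants = nrow(res), alpha = alpha,
    n_nominal_nonadditive = sum(res$nominal_nonadditive),
    n_full_dom_or_rec = sum(res$full_dom_or_rec),
    n_forwarded = length(fwd),
    n_replicated_nominal = sum(res$replicated_nominal),
    n_replicated_bonferroni = sum(res$replicated_bonferroni),
    n_untestable = sum(res$repl_untestable),
    bonferroni_discovery = bonferroni_threshold(alpha, nrow(res)),
    bonferroni_replication = bon_repl,
    expected_by_chance = expected_by_chance(length(fwd), alpha))
  structure(list(results = res, summary = summary), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat("<screen_result>\n")
  cat(sprintf("  %d variants tested in discovery (alpha = %g)\n",
              s$n_variants, s$alpha))
  cat(sprintf("  nominal non-additive: %d; full dom/rec consistent: %d\n",
              s$n_nominal_nonadditive, s$n_full_dom_or_rec))
  cat(sprintf("  forwarded to replication: %d (expected by chance to replicate: %.2f)\n",
              s$n_forwarded, s$expected_by_chance))
  cat(sprintf("  replicated: %d nominal, %d after Bonferroni (p < %s)\n",
              s$n_replicated_nominal, s$n_replicated_bonferroni,
              format(s$bonferroni_replication, digits = 3)))
  invisible(x)
}

#' Write the screen results table
#'
#' Tab-separated, mirroring the standard two-stage association table layout
#' (variant, MAF, discovery additive and dominance-deviation triplets, the
#' two genotypic contrast p-values, replication triplets) plus the stage
#' flags.
#'
#' @param screen a `"screen_result"`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_screen_table <- function(screen, path) {
  utils::write.table(screen$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
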