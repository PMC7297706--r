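#' Build polygenic risk score weights
#'
#' Three constructions from discovery-sample fits:
#' * `prs1` — the conventional additive score: per-variant betas from an
#'   additive-only refit (no dominance-deviation term), all gamma weights 0.
#' * `prs2` — dominance-aware for every variant: joint (beta, gamma) from
#'   the full dominance-deviation fit.
#' * `prs3` — dominance-aware only for a selected subset with robust
#'   non-additive evidence: those variants carry their joint (beta, gamma);
#'   all others keep the `prs1` beta with gamma 0.
#'
#' The discovery weights are log-odds from a binary-myopia fit even though
#' the score is later used to predict continuous refractive error; this
#' scale mismatch is deliberate (weights transfer by rank/shape, and the
#' evaluation is variance explained, which is scale-free).
#'
#' @param additive_fits data.frame with `variant_id`, `beta` from an
#'   additive-only [assoc_scan()] (`dominance = FALSE`).
#' @param domdev_fits data.frame with `variant_id`, `beta`, `gamma` from the
#'   full dominance-deviation scan.
#' @param mode `"prs1"`, `"prs2"` or `"prs3"`.
#' @param selected variant ids carrying dominance weights under `prs3`.
#' @return data.frame of class `"prs_weights"` with `variant_id`,
#'   `beta_weight`, `gamma_weight`; attributes `source` and
#'   `selected_nonadditive`.
#' @export
build_prs_weights <- function(additive_fits, domdev_fits = NULL,
                              mode = c("prs1", "prs2", "prs3"),
                              selected = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("prs2", "prs3") && is.null(domdev_fits)) {
    stop("domdev_fits required for ", mode)
  }
  ids <- additive_fits$variant_id
  w <- switch(mode,
    prs1 = data.frame(variant_id = ids, beta_weight = additive_fits$beta,
                      gamma_weight = 0),
    prs2 = {
      m <- match(ids, domdev_fits$variant_id)
      if (anyNA(m)) stop("missing joint fits for: ",
                         paste(ids[is.na(m)], collapse = ", "))
      data.frame(variant_id = ids, beta_weight = domdev_fits$beta[m],
                 gamma_weight = domdev_fits$gamma[m])
    },
    prs3 = {
      if (is.null(selected) || length(selected) == 0) {
        # empty selection degenerates to the conventional score
        data.frame(variant_id = ids, beta_weight = additive_fits$beta,
                   gamma_weight = 0)
      } else {
        m <- match(selected, domdev_fits$variant_id)
        if (anyNA(m)) stop("selected variant(s) missing a joint fit: ",
                           paste(selected[is.na(m)], collapse = ", "))
        out <- data.frame(variant_id = ids,
                          beta_weight = additive_fits$beta,
                          gamma_weight = 0)
        k <- match(selected, ids)
        if (anyNA(k)) stop("selected variant(s) not in panel: ",
                           paste(selected[is.na(k)], collapse = ", "))
        out$beta_weight[k] <- domdev_fits$beta[m]
        out$gamma_weight[k] <- domdev_fits$gamma[m]
        out
      }
    })
  structure(w, source = switch(mode, prs1 = "additive_fit",
                               prs2 = "domdev_fit", prs3 = "mixed"),
            selected_nonadditive = selected, mode = mode,
            class = c("prs_weights", "data.frame"))
}

#' Compute polygenic risk scores
#'
#' `score_i = sum_k beta_k * add_k,i + sum_k gamma_k * domdev_k,i` over the
#' weight variants, with the additive coding the minor-allele count and the
#' dominance coding the heterozygosity indicator. A missing genotype
#' contributes the variant's sample-mean coding values (mean imputation
#' keeps n constant across score variants).
#'
#' @param weights a `"prs_weights"` (or data.frame with `variant_id`,
#'   `beta_weight`, `gamma_weight`).
#' @param genotypes individuals x variants matrix containing (at least) the
#'   weight variants, minor-allele oriented to match the weights.
#' @return numeric score vector, one per individual.
#' @export
compute_prs <- function(weights, genotypes) {
  miss <- setdiff(weights$variant_id, colnames(genotypes))
  if (length(miss)) {
    stop("weight variants absent from genotypes (orientation/panel mismatch): ",
         paste(miss, collapse = ", "))
  }
  G <- genotypes[, weights$variant_id, drop = FALSE]
  storage.mode(G) <- "double"
  H <- (G == 1) * 1
  if (anyNA(G)) {
    gm <- colMeans(G, na.rm = TRUE)
    hm <- colMeans(H, na.rm = TRUE)
    na <- which(is.na(G))
    G[na] <- gm[(na - 1) %/% nrow(G) + 1]
    H[na] <- hm[(na - 1) %/% nrow(G) + 1]
  }
  as.vector(G %*% weights$beta_weight + H %*% weights$gamma_weight)
}

adj_r2 <- function(X, y) {
  n <- length(y); p <- ncol(X) - 1  # X includes intercept
  fit <- stats::.lm.fit(X, y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Evaluate incremental variance explained by a polygenic score
#'
#' The variance in refractive error explained by a score is the adjusted R^2
#' of `outcome ~ age + gender + score` minus the adjusted R^2 of the
#' baseline `outcome ~ age + gender`. The 95% confidence interval is a
#' percentile bootstrap over individuals (default 2000 resamples),
#' deterministic given `seed`.
#'
#' @param score numeric PRS vector.
#' @param refractive_error outcome vector (dioptres).
#' @param age,gender baseline covariates.
#' @param n_bootstrap bootstrap resamples (>= 1).
#' @param seed RNG seed for resampling.
#' @param conf confidence level (default 0.95).
#' @return object of class `"prs_evaluation"`: `r2_delta`, `ci_low`,
#'   `ci_high`, `baseline_r2`, `n`, `n_bootstrap`, `seed`.
#' @export
evaluate_prs <- function(score, refractive_error, age, gender,
                         n_bootstrap = 2000, seed = 1L, conf = 0.95) {
  n <- length(refractive_error)
  stopifnot(n >= 30, n_bootstrap >= 1, length(score) == n,
            length(age) == n, length(gender) == n)
  Xb <- cbind(1, age, gender)
  Xf <- cbind(Xb, score)
  base <- adj_r2(Xb, refractive_error)
  delta <- adj_r2(Xf, refractive_error) - base
  local_rng(seed)
  boots <- vapply(seq_len(n_bootstrap), function(b) {
    i <- sample.int(n, replace = TRUE)
    adj_r2(Xf[i, , drop = FALSE], refractive_error[i]) -
      adj_r2(Xb[i, , drop = FALSE], refractive_error[i])
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(r2_delta = delta, ci_low = qs[1], ci_high = qs[2],
                 baseline_r2 = base, n = n, n_bootstrap = n_bootstrap,
                 seed = seed, conf = conf, bootstrap_type = "percentile"),
            class = "prs_evaluation")
}

#' @export
print.prs_evaluation <- function(x, ...) {
  cat(sprintf(
    "<prs_evaluation> incremental adj-R^2 = %.4f (%.0f%% CI %.4f to %.4f; %d bootstraps, n = %d)\n",
    x$r2_delta, 100 * x$conf, x$ci_low, x$ci_high, x$n_bootstrap, x$n))
  invisible(x)
}

#' Read / write PRS weights
#'
#' Tab-separated `variant_id  beta  gamma  source`.
#'
#' @param weights a `"prs_weights"`.
#' @param path file path.
#' @return `read_prs_weights()` returns a `"prs_weights"` data.frame.
#' @export
write_prs_weights <- function(weights, path) {
  out <- data.frame(variant_id = weights$variant_id,
                    beta = weights$beta_weight,
                    gamma = weights$gamma_weight,
                    source = attr(weights, "source") %||% "unknown")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prs_weights
#' @export
read_prs_weights <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(data.frame(variant_id = d$variant_id, beta_weight = d$beta,
                       gamma_weight = d$gamma),
            source = d$source[1], class = c("prs_weights", "data.frame"))
}
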