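#' Fit the AOSW myopia classifier
#'
#' In individuals with both a measured refractive error and a known age of
#' onset of spectacle wear (AOSW), myopia status (refractive error at or
#' below `myopia_cut`) is regressed on AOSW by maximum-likelihood logistic
#' regression. Two predicted-probability thresholds are then read off the
#' empirical ROC curve: `threshold_spec90`, the least extreme cut at which
#' calling "myopic" achieves at least 90% specificity, and
#' `threshold_sens90`, the least extreme cut at which it retains at least
#' 90% sensitivity (so that calling "non-myopic" below it misses at most 10%
#' of myopes). Among tied cuts the one maximizing the complementary metric
#' is chosen. Individuals whose predicted probability falls strictly between
#' the two cuts cannot be classified.
#'
#' When the data are so well separated that the two criteria cross
#' (`threshold_spec90 < threshold_sens90`), both thresholds are collapsed to
#' the specificity cut and no individual is left unclassified.
#'
#' @param refractive_error dioptre vector.
#' @param aosw years vector (NA = unknown / never wore spectacles).
#' @param myopia_cut dioptre threshold defining myopia; default -0.75 D
#'   (mean spherical equivalent), a common epidemiological definition —
#'   configurable because the operational cut is study-specific.
#' @param specificity,sensitivity targets for the two cuts (default 0.90).
#' @return object of class `"aosw_classifier"`: coefficients (intercept and
#'   AOSW slope on the log-odds scale), the two thresholds, achieved
#'   sensitivity/specificity at each, `myopia_cut` and fit metadata.
#' @export
fit_aosw_classifier <- function(refractive_error, aosw, myopia_cut = -0.75,
                                specificity = 0.90, sensitivity = 0.90) {
  keep <- !is.na(refractive_error) & !is.na(aosw)
  re <- refractive_error[keep]; a <- aosw[keep]
  y <- as.integer(re <= myopia_cut)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least 2 individuals in each myopia class")
  }
  fit <- suppressWarnings(
    stats::glm(y ~ a, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged) stop("AOSW logistic fit did not converge (deviance ",
                           format(fit$deviance), ")")
  p <- stats::fitted(fit)

  # Empirical ROC over all candidate probability cuts: "myopic" iff p >= c.
  cuts <- sort(unique(p))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  ord <- order(p)
  ps <- p[ord]; ys <- y[ord]
  # counts of cases/controls with p < c, for c running over `cuts`
  idx <- findInterval(cuts, ps, left.open = TRUE) # entries strictly below c
  cum1 <- cumsum(ys); cum0 <- cumsum(1 - ys)
  below1 <- ifelse(idx == 0, 0, cum1[pmax(idx, 1)])
  below0 <- ifelse(idx == 0, 0, cum0[pmax(idx, 1)])
  sens <- (n1 - below1) / n1   # P(p >= c | myopic)
  spec <- below0 / n0          # P(p < c  | non-myopic)

  ok_spec <- spec >= specificity
  if (!any(ok_spec)) stop("no cut achieves the target specificity")
  t_spec <- min(cuts[ok_spec])  # least extreme; maximizes sensitivity
  ok_sens <- sens >= sensitivity
  if (!any(ok_sens)) stop("no cut achieves the target sensitivity")
  t_sens <- max(cuts[ok_sens])  # least extreme; maximizes specificity
  if (t_spec < t_sens) t_sens <- t_spec  # over-separated data: collapse band

  at <- function(cut) {
    c(sensitivity = mean(p[y == 1] >= cut), specificity = mean(p[y == 0] < cut))
  }
  structure(list(
    coefficients = stats::coef(fit),
    threshold_spec90 = t_spec, threshold_sens90 = t_sens,
    achieved_at_spec_cut = at(t_spec), achieved_at_sens_cut = at(t_sens),
    myopia_cut = myopia_cut, specificity_target = specificity,
    sensitivity_target = sensitivity, n = length(y), n_myopic = n1
  ), class = "aosw_classifier")
}

#' Classify individuals by AOSW
#'
#' Applies the fitted logistic model and the dual ROC thresholds: predicted
#' myopia probability at or above `threshold_spec90` gives `"myopic"`, at or
#' below `threshold_sens90` gives `"non_myopic"`, anything strictly between
#' is `"unclassified"` (and should be excluded from downstream association
#' fits). Missing AOSW yields `"unclassified"` unless the individual is
#' flagged a never-wearer, in which case a sentinel late-onset AOSW
#' (`sentinel_aosw`, default 60 years) is substituted so such individuals
#' can qualify as non-myopic.
#'
#' @param classifier an `"aosw_classifier"`.
#' @param aosw years vector.
#' @param never_wearer optional logical vector marking individuals known to
#'   have never worn spectacles.
#' @param sentinel_aosw AOSW value imputed for never-wearers.
#' @return factor with levels `myopic`, `non_myopic`, `unclassified`.
#' @export
classify <- function(classifier, aosw, never_wearer = NULL,
                     sentinel_aosw = 60) {
  stopifnot(inherits(classifier, "aosw_classifier"))
  if (!is.null(never_wearer)) {
    aosw[!is.na(never_wearer) & never_wearer] <- sentinel_aosw
  }
  b <- classifier$coefficients
  p <- stats::plogis(b[1] + b[2] * aosw)
  lab <- rep("unclassified", length(aosw))
  lab[!is.na(p) & p >= classifier$threshold_spec90] <- "myopic"
  lab[!is.na(p) & p <= classifier$threshold_sens90 &
        lab != "myopic"] <- "non_myopic"
  factor(lab, levels = c("myopic", "non_myopic", "unclassified"))
}

#' @export
print.aosw_classifier <- function(x, ...) {
  cat("<aosw_classifier>\n")
  cat(sprintf("  logit P(myopia) = %.4f + %.4f * AOSW   (n = %d, %d myopic)\n",
              x$coefficients[1], x$coefficients[2], x$n, x$n_myopic))
  cat(sprintf("  myopia cut: refractive error <= %.2f D\n", x$myopia_cut))
  cat(sprintf("  p >= %.4f -> myopic      (spec %.3f, sens %.3f)\n",
              x$threshold_spec90, x$achieved_at_spec_cut["specificity"],
              x$achieved_at_spec_cut["sensitivity"]))
  cat(sprintf("  p <= %.4f -> non-myopic  (spec %.3f, sens %.3f)\n",
              x$threshold_sens90, x$achieved_at_sens_cut["specificity"],
              x$achieved_at_sens_cut["sensitivity"]))
  invisible(x)
}

#' Serialize / restore an AOSW classifier
#'
#' Plain-text key-value (DCF) format so classifiers can be shared between
#' runs and inspected by eye.
#'
#' @param classifier an `"aosw_classifier"`.
#' @param path file path.
#' @return `read_aosw_classifier()` returns the restored classifier.
#' @export
write_aosw_classifier <- function(classifier, path) {
  d <- data.frame(
    intercept = classifier$coefficients[1],
    slope = classifier$coefficients[2],
    threshold_spec90 = classifier$threshold_spec90,
    threshold_sens90 = classifier$threshold_sens90,
    myopia_cut = classifier$myopia_cut,
    specificity_target = classifier$specificity_target,
    sensitivity_target = classifier$sensitivity_target,
    n = classifier$n, n_myopic = classifier$n_myopic)
  write.dcf(format(d, digits = 17), path)
  invisible(path)
}

#' @rdname write_aosw_classifier
#' @export
read_aosw_classifier <- function(path) {
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  d[] <- lapply(d, as.numeric)
  structure(list(
    coefficients = c(`(Intercept)` = d$intercept, a = d$slope),
    threshold_spec90 = d$threshold_spec90,
    threshold_sens90 = d$threshold_sens90,
    achieved_at_spec_cut = c(sensitivity = NA_real_, specificity = NA_real_),
    achieved_at_sens_cut = c(sensitivity = NA_real_, specificity = NA_real_),
    myopia_cut = d$myopia_cut, specificity_target = d$specificity_target,
    sensitivity_target = d$sensitivity_target, n = as.integer(d$n),
    n_myopic = as.integer(d$n_myopic)), class = "aosw_classifier")
}
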