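#' Construct a variant panel
#'
#' A variant panel holds the per-variant metadata the whole pipeline works
#' from: alleles, minor-allele frequency (MAF), and the true (or estimated)
#' additive and dominance-deviation effects. The genotypic value of genotype
#' `g` (minor-allele count 0/1/2) at a variant is parameterised as
#' `beta * g + gamma * (g == 1)`, so `gamma` is the departure of the
#' heterozygote from the additive expectation (the dominance deviation):
#' complete dominance of the minor allele corresponds to `gamma == beta`
#' (heterozygote sits at the minor-homozygote value `2 * beta`) and complete
#' recessiveness to `gamma == -beta`.
#'
#' @param variant_id character vector of unique variant identifiers.
#' @param maf numeric vector of minor-allele frequencies in (0, 0.5].
#' @param beta_true additive effect per minor allele (dioptres, or log-odds
#'   for binary traits).
#' @param gamma_true dominance-deviation effect, same units as `beta_true`.
#'   May be `NA` when `mode` determines it (additive/dominant/recessive).
#' @param mode one of `"additive"`, `"dominant"`, `"recessive"`, `"custom"`,
#'   recycled across variants. For the first three, `gamma_true` is filled in
#'   (0, `beta_true`, `-beta_true` respectively) and checked if supplied.
#' @param gene_label,major_allele,minor_allele optional annotation columns.
#' @return A `data.frame` of class `"variant_panel"` with columns
#'   `variant_id`, `gene_label`, `major_allele`, `minor_allele`, `maf`,
#'   `beta_true`, `gamma_true`, `mode`.
#' @export
variant_panel <- function(variant_id, maf, beta_true, gamma_true = NA_real_,
                          mode = "custom", gene_label = NA_character_,
                          major_allele = "A", minor_allele = "B") {
  n <- length(variant_id)
  if (anyDuplicated(variant_id)) stop("duplicate variant_id in panel")
  maf <- as.numeric(maf)
  if (length(maf) != n) stop("maf must have one entry per variant")
  bad <- !is.finite(maf) | maf <= 0 | maf > 0.5
  if (any(bad)) {
    stop("invalid MAF (must be finite, in (0, 0.5]) for variant(s): ",
         paste(variant_id[bad], collapse = ", "))
  }
  mode <- rep_len(match.arg(mode, c("additive", "dominant", "recessive",
                                    "custom"), several.ok = TRUE), n)
  beta_true <- rep_len(as.numeric(beta_true), n)
  gamma_true <- rep_len(as.numeric(gamma_true), n)
  implied <- ifelse(mode == "additive", 0,
             ifelse(mode == "dominant", beta_true,
             ifelse(mode == "recessive", -beta_true, NA_real_)))
  fill <- is.na(gamma_true) & !is.na(implied)
  gamma_true[fill] <- implied[fill]
  mismatch <- !is.na(implied) & abs(gamma_true - implied) > 1e-12
  if (any(mismatch)) {
    stop("gamma_true inconsistent with mode for variant(s): ",
         paste(variant_id[mismatch], collapse = ", "))
  }
  if (anyNA(gamma_true)) stop("gamma_true required for mode = 'custom'")
  panel <- data.frame(
    variant_id = as.character(variant_id),
    gene_label = rep_len(as.character(gene_label), n),
    major_allele = rep_len(as.character(major_allele), n),
    minor_allele = rep_len(as.character(minor_allele), n),
    maf = maf, beta_true = beta_true, gamma_true = gamma_true,
    mode = mode, stringsAsFactors = FALSE
  )
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

#' Default 146-variant panel
#'
#' Draws a panel emulating the screened refractive-error variant set: MAFs
#' uniform on (0.03, 0.5) (mirroring the MAF > 0.03 inclusion filter) and
#' additive-effect magnitudes uniform on 0.02-0.33 dioptres per allele with
#' random sign. Absolute effect scale is immaterial downstream because
#' phenotype simulation rescales the genetic component to a target variance
#' explained; only the joint MAF-effect distribution matters.
#'
#' @param n_variants panel size (default 146).
#' @param mode genetic architecture passed to [variant_panel()].
#' @param maf_range,beta_range uniform sampling ranges.
#' @param seed integer seed; the panel is deterministic given it.
#' @return a `variant_panel`.
#' @export
default_panel <- function(n_variants = 146, mode = "additive",
                          maf_range = c(0.03, 0.5),
                          beta_range = c(0.02, 0.33), seed = 1L) {
  stopifnot(n_variants >= 1)
  rs <- local_rng(seed)
  maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
  beta <- stats::runif(n_variants, beta_range[1], beta_range[2]) *
    sample(c(-1, 1), n_variants, replace = TRUE)
  variant_panel(
    variant_id = sprintf("var%03d", seq_len(n_variants)),
    maf = maf, beta_true = beta, mode = mode,
    gene_label = sprintf("GENE%03d", seq_len(n_variants))
  )
}

#' Per-variant genotypic values and population variance
#'
#' `genotypic_values()` returns the three genotype-class values
#' (g = 0, 1, 2) implied by a panel row; `panel_genetic_variance()` the
#' Hardy-Weinberg population variance of the summed genetic component
#' (variants independent, no linkage disequilibrium).
#'
#' @param panel a `variant_panel`.
#' @return `genotypic_values()`: an `n x 3` matrix; the variance helper a
#'   single number.
#' @export
genotypic_values <- function(panel) {
  cbind(v0 = 0, v1 = panel$beta_true + panel$gamma_true,
        v2 = 2 * panel$beta_true)
}

#' @rdname genotypic_values
#' @export
panel_genetic_variance <- function(panel) {
  q <- panel$maf
  p0 <- (1 - q)^2; p1 <- 2 * q * (1 - q); p2 <- q^2
  v <- genotypic_values(panel)
  m <- p0 * v[, 1] + p1 * v[, 2] + p2 * v[, 3]
  m2 <- p0 * v[, 1]^2 + p1 * v[, 2]^2 + p2 * v[, 3]^2
  sum(m2 - m^2)
}

#' Additive share of genetic variance under complete dominance
#'
#' For a single biallelic variant with complete dominance of the minor allele
#' (heterozygote equal to the minor homozygote) at MAF `p`, the fraction of
#' its genetic variance captured by the best additive (allele-count)
#' predictor is `2(1 - p) / (2(1 - p) + p)` — e.g. 0.889 at `p = 0.2`. This
#' closed form is what bounds additive polygenic-score accuracy when the
#' truth is dominant.
#'
#' @param maf minor-allele frequency vector in (0, 0.5].
#' @return numeric vector of additive variance shares in (0, 1).
#' @export
dominant_additive_share <- function(maf) {
  stopifnot(all(maf > 0 & maf <= 0.5))
  2 * (1 - maf) / (2 * (1 - maf) + maf)
}

#' Read / write a variant panel file
#'
#' Tab-separated with header
#' `variant_id  gene  major  minor  maf  beta  gamma  mode`, the interchange
#' format for supplying externally estimated per-variant MAFs and effects.
#'
#' @param path file path.
#' @param panel a `variant_panel` (for writing).
#' @return `read_panel()` returns a `variant_panel`; `write_panel()` its
#'   `path`, invisibly.
#' @export
read_panel <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "gene", "major", "minor", "maf", "beta", "gamma",
            "mode")
  if (!all(need %in% names(d))) {
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  }
  variant_panel(d$variant_id, maf = d$maf, beta_true = d$beta,
                gamma_true = d$gamma, mode = d$mode, gene_label = d$gene,
                major_allele = d$major, minor_allele = d$minor)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(variant_id = panel$variant_id, gene = panel$gene_label,
                    major = panel$major_allele, minor = panel$minor_allele,
                    maf = panel$maf, beta = panel$beta_true,
                    gamma = panel$gamma_true, mode = panel$mode)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Seed the generator for a simulation entry point; NULL leaves the stream as
# is. Sub-seeds derived from a master seed stay below 2^31 - 1.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(seed)
}

derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483647L)
}
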