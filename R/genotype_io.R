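#' Convert imputed dosages to hard-call genotypes
#'
#' A dosage in `[0, 2]` becomes the nearest integer genotype `g` when
#' `|dosage - g| <= threshold` (ties at the exact threshold distance are
#' called, matching the behaviour of the standard `--hard-call-threshold`
#' conversion); otherwise the genotype is set missing (`NA`).
#'
#' @param dosage numeric vector of expected minor-allele counts in `[0, 2]`
#'   (`NA` passes through as missing).
#' @param threshold maximum distance to an integer, in `(0, 0.5)`;
#'   default 0.1.
#' @return integer vector in `{0, 1, 2, NA}`.
#' @export
hard_call <- function(dosage, threshold = 0.1) {
  stopifnot(threshold > 0, threshold < 0.5)
  ok <- is.na(dosage) | (dosage >= 0 & dosage <= 2)
  if (!all(ok)) {
    stop("dosage outside [0, 2] at position(s): ",
         paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  g <- round(dosage)
  # small epsilon so ties at exactly threshold distance survive float noise
  g[!is.na(dosage) & abs(dosage - g) - threshold > 1e-9] <- NA
  as.integer(g)
}

#' Minor-allele frequency of a genotype column
#'
#' Frequency of the counted allele over non-missing entries,
#' `sum(g) / (2 * n)`, orientation-corrected to be at most 0.5. When the
#' counted allele turns out to be the major one the returned value is the
#' flipped frequency and the `"flipped"` attribute is `TRUE` (the column
#' itself is not modified; see [orient_minor()]).
#'
#' @param g integer genotype vector in `{0, 1, 2, NA}`.
#' @return MAF in `[0, 0.5]` with logical attribute `"flipped"`.
#' @export
minor_allele_frequency <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0) stop("all-missing genotype column")
  stopifnot(all(g %in% 0:2))
  af <- sum(g) / (2 * length(g))
  flipped <- af > 0.5
  structure(if (flipped) 1 - af else af, flipped = flipped)
}

#' Orient a genotype matrix to count minor alleles
#'
#' Recodes columns whose counted-allele frequency exceeds 0.5 as `2 - g`, so
#' every column counts the allele with frequency <= 0.5 in this sample.
#' Orientation should be fixed on the combined sample before any
#' discovery/replication split so coefficient signs are comparable across
#' stages.
#'
#' @param genotypes individuals x variants integer matrix.
#' @return the oriented matrix, with logical attribute `"flipped"` (one
#'   entry per variant).
#' @export
orient_minor <- function(genotypes) {
  af <- colMeans(genotypes, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) genotypes[, flip] <- 2L - genotypes[, flip]
  attr(genotypes, "flipped") <- flip
  genotypes
}

#' Apply the MAF inclusion filter
#'
#' Keeps variants whose minor-allele frequency is strictly greater than
#' `min_maf` (the screening filter uses MAF > 0.03, chosen so the
#' replication sample is expected to contain at least 50 minor-allele
#' homozygotes).
#'
#' @param genotypes individuals x variants matrix with variant ids as
#'   `colnames`.
#' @param min_maf threshold in `[0, 0.5]`.
#' @return list with `genotypes` (kept columns) and `report`, a data.frame
#'   of `variant_id`, `maf`, `kept`.
#' @export
apply_maf_filter <- function(genotypes, min_maf = 0.03) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  mafs <- vapply(seq_len(ncol(genotypes)), function(j)
    as.numeric(minor_allele_frequency(genotypes[, j])), numeric(1))
  keep <- mafs > min_maf
  report <- data.frame(
    variant_id = colnames(genotypes) %||% as.character(seq_along(mafs)),
    maf = mafs, kept = keep, stringsAsFactors = FALSE)
  list(genotypes = genotypes[, keep, drop = FALSE], report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genotype codings for non-additive effect models
#'
#' Expands a hard-call genotype into the three codings the association
#' models use: `snp_add`, the minor-allele count (0/1/2); `snp_domdev`, the
#' heterozygosity indicator (1 for AB, 0 otherwise); and `snp_cat`, the
#' genotype as a factor with the heterozygote as the reference category
#' (levels AB, AA, BB). Missing genotypes propagate to `NA` in all three.
#'
#' @param g integer genotype vector in `{0, 1, 2, NA}`.
#' @return data.frame with columns `snp_add`, `snp_domdev`, `snp_cat`.
#' @export
encode_codings <- function(g) {
  stopifnot(all(is.na(g) | g %in% 0:2))
  data.frame(
    snp_add = as.integer(g),
    snp_domdev = as.integer(g == 1L),
    snp_cat = factor(c("AA", "AB", "BB")[g + 1L], levels = c("AB", "AA", "BB"))
  )
}

#' Read / write genotype matrices as tab-separated text
#'
#' Layout: one row per individual, first column `individual_id`, remaining
#' columns one variant each, entries 0/1/2 or `NA`. The round trip is
#' lossless.
#'
#' @param genotypes integer matrix with individual ids as `rownames`.
#' @param path file path.
#' @return `read_genotypes()`: an integer matrix; `write_genotypes()`: the
#'   path, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  d <- data.frame(individual_id = rownames(genotypes) %||%
                    sprintf("ind%06d", seq_len(nrow(genotypes))),
                  genotypes, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = list(individual_id = "character"))
  G <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- d$individual_id
  G
}

#' Read genotypes from a VCF file
#'
#' Uses hard GT calls when present; otherwise converts DS dosages via
#' [hard_call()]. Columns are oriented to count minor alleles. Multi-allelic
#' records are an error (out of scope).
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param hard_call_threshold dosage threshold passed to [hard_call()].
#' @return integer matrix individuals x variants, oriented, with the
#'   `"flipped"` attribute from [orient_minor()].
#' @export
read_vcf_genotypes <- function(path, hard_call_threshold = 0.1) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VariantAnnotation is required to read VCF files")
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1)) stop("multi-allelic variants are not supported")
  geno <- VariantAnnotation::geno(vcf)
  if ("GT" %in% names(geno)) {
    gt <- geno$GT
    G <- matrix(NA_integer_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
    map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
    G[] <- map[t(gt)]
  } else if ("DS" %in% names(geno)) {
    ds <- geno$DS
    G <- matrix(hard_call(as.numeric(t(ds)), hard_call_threshold),
                ncol(ds), nrow(ds),
                dimnames = list(colnames(ds), rownames(ds)))
  } else {
    stop("VCF has neither GT nor DS genotype fields")
  }
  orient_minor(G)
}

#' Read genotypes from PLINK text pedigree files
#'
#' Minimal reader for `.ped`/`.map` pairs with biallelic variants; allele
#' pairs are converted to minor-allele counts using the sample allele
#' frequencies. `0` alleles are treated as missing.
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @return oriented integer genotype matrix (individuals x variants).
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, stringsAsFactors = FALSE)
  ped <- utils::read.table(ped_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) stop(".ped column count does not match .map")
  ids <- ped[[2]]
  G <- matrix(NA_integer_, nrow(ped), m, dimnames = list(ids, map[[2]]))
  for (j in seq_len(m)) {
    a1 <- ped[[6 + 2 * j - 1]]; a2 <- ped[[6 + 2 * j]]
    alleles <- setdiff(unique(c(a1, a2)), "0")
    if (length(alleles) > 2) {
      stop("multi-allelic variant in .ped: ", map[[2]][j])
    }
    if (length(alleles) == 0) next
    ref <- alleles[1]
    miss <- a1 == "0" | a2 == "0"
    g <- (a1 != ref) + (a2 != ref)
    g[miss] <- NA
    G[, j] <- as.integer(g)
  }
  orient_minor(G)
}
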