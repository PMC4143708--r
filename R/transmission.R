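# Mendelian transmission law for autosomal biallelic variants under additive
# dosage coding: conditional offspring genotype distributions given parental
# dosages, their means/variances, parental allele frequencies, and Beta-density
# variant weights.

#' Conditional offspring dosage distribution given parental dosages
#'
#' For an autosomal biallelic variant with additive coding (dosage = number of
#' copies of the coded allele), each parent transmits one allele independently;
#' a heterozygous parent transmits the coded allele with probability 1/2.
#'
#' @param gf,gm Paternal and maternal dosages, each in \{0, 1, 2\}. Vectors are
#'   recycled to common length.
#' @return A tibble with columns `gf`, `gm`, `p0`, `p1`, `p2` giving
#'   P(offspring dosage = k | gf, gm).
#' @examples
#' offspring_distribution(1, 1) # 1/4, 1/2, 1/4
#' @export
offspring_distribution <- function(gf, gm) {
  check_dosage(gf)
  check_dosage(gm)
  n <- max(length(gf), length(gm))
  gf <- rep_len(gf, n)
  gm <- rep_len(gm, n)
  # per-parent probability of transmitting the coded allele
  tf <- gf / 2
  tm <- gm / 2
  tibble(
    gf = gf, gm = gm,
    p0 = (1 - tf) * (1 - tm),
    p1 = tf * (1 - tm) + (1 - tf) * tm,
    p2 = tf * tm
  )
}

#' Expected offspring dosage given parental dosages
#'
#' Mean of [offspring_distribution()]; equals (gf + gm) / 2.
#'
#' @inheritParams offspring_distribution
#' @return Numeric vector of conditional expectations in \[0, 2\].
#' @export
expected_dosage <- function(gf, gm) {
  check_dosage(gf)
  check_dosage(gm)
  (gf + gm) / 2
}

#' Conditional variance of offspring dosage given parental dosages
#'
#' Each heterozygous parent contributes 1/4; homozygous parents contribute 0.
#' Missing parental dosages (NA) give variance 0, matching the convention that
#' uninformative trio-variant cells are zeroed out of the score.
#'
#' @inheritParams offspring_distribution
#' @return Numeric vector of conditional variances in \{0, 1/4, 1/2\}.
#' @export
dosage_variance <- function(gf, gm) {
  check_dosage(gf)
  check_dosage(gm)
  v <- 0.25 * ((gf == 1) + (gm == 1))
  v[is.na(v)] <- 0
  v
}

check_dosage <- function(g) {
  bad <- !is.na(g) & !(g %in% c(0, 1, 2))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; got: ",
         paste(unique(g[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(g)
}

#' Full Mendelian transmission table
#'
#' Enumerates the conditional offspring dosage distribution and its mean for
#' all nine ordered parental dosage pairs.
#'
#' @return A tibble with columns `gf`, `gm`, `p0`, `p1`, `p2`, `mean`, `var`.
#' @export
transmission_table <- function() {
  g <- expand.grid(gf = 0:2, gm = 0:2)
  out <- offspring_distribution(g$gf, g$gm)
  out$mean <- expected_dosage(g$gf, g$gm)
  out$var <- dosage_variance(g$gf, g$gm)
  out
}

#' Parental minor-allele frequency per variant
#'
#' Estimates each variant's coded-allele frequency from the parents only:
#' coded-allele count over twice the number of non-missing parental genotypes.
#' After minor-allele recoding (see [trio_cohort()]) these lie in \[0, 0.5\].
#'
#' @param paternal,maternal N x m dosage matrices (trios by variants), NA for
#'   missing.
#' @return Numeric vector of length m; NA (with a warning) for variants where
#'   every parental genotype is missing — such variants are untestable.
#' @export
parental_maf <- function(paternal, maternal) {
  stopifnot(identical(dim(paternal), dim(maternal)))
  alleles <- colSums(paternal, na.rm = TRUE) + colSums(maternal, na.rm = TRUE)
  n_obs <- colSums(!is.na(paternal)) + colSums(!is.na(maternal))
  f <- ifelse(n_obs > 0, alleles / (2 * n_obs), NA_real_)
  if (anyNA(f)) {
    warning(sum(is.na(f)), " variant(s) have no non-missing parental genotypes; ",
            "frequency undefined (NA), excluded from testing", call. = FALSE)
  }
  unname(f)
}

#' Beta-density variant weights
#'
#' Weight w_j = dbeta(f_j; a, b), the Beta density evaluated at the parental
#' minor-allele frequency. The default (a = 1, b = 25) upweights rare variants
#' sharply; a = b = 1 gives unweighted (flat) tests.
#'
#' @param f Parental minor-allele frequencies in (0, 1).
#' @param a,b Positive Beta shape parameters.
#' @return Nonnegative weights, one per frequency.
#' @export
beta_weights <- function(f, a = 1, b = 25) {
  stopifnot(a > 0, b > 0)
  if ((a < 1 && any(!is.na(f) & f <= 0)) || (b < 1 && any(!is.na(f) & f >= 1))) {
    stop("monomorphic variants (f = 0) give infinite Beta weights for a < 1; ",
         "exclude them before weighting", call. = FALSE)
  }
  stats::dbeta(f, a, b)
}
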