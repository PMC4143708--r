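# The transmission-conditioned score test. Under the generalized linear
# mixed model h(mu_i) = C_i alpha + X_i beta with random variant effects
# beta_j ~ (0, w_j^2 tau), the region-level null H0: tau = 0 is tested with
# the quadratic form
#     Q_rho = (Y - mu0)' (X - E[X|Xp]) W R_rho W (X - E[X|Xp])' (Y - mu0),
# where E[X|Xp] is the Mendelian expectation of the offspring dosage given
# the parents, W = diag(w_j) holds Beta-density MAF weights, and
# R_rho = (1 - rho) I + rho 11' interpolates between the variance-component
# kernel (rho = 0, SKAT) and the FBAT-style burden kernel (rho = 1).
# Conditioning on parental genotypes makes the null distribution immune to
# population structure: only the randomness of transmission is used.

#' Fit the null (no genetic effect) trait model
#'
#' Continuous traits: least squares of Y on the covariates C. Dichotomous
#' traits: logistic maximum likelihood. The fitted means mu0 and residuals
#' Y - mu0 feed the score statistic.
#'
#' @param y Trait vector (length N). Dichotomous traits must be 0/1.
#' @param covariates N x p covariate matrix including an intercept column,
#'   or NULL for intercept only.
#' @param trait_type "continuous" or "dichotomous".
#' @return A `trio_null_model`: list with `alpha_hat`, `mu0`, `residuals`,
#'   `trait_type`, `covariates`.
#' @export
fit_null_model <- function(y, covariates = NULL,
                           trait_type = c("continuous", "dichotomous")) {
  trait_type <- match.arg(trait_type)
  n <- length(y)
  if (is.null(covariates)) {
    covariates <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  if (qr(covariates)$rank < ncol(covariates)) {
    stop("covariate matrix is rank deficient", call. = FALSE)
  }
  if (n < ncol(covariates) + 1) {
    stop("need more trios than covariates", call. = FALSE)
  }
  if (trait_type == "continuous") {
    fit <- lm.fit(covariates, y)
    alpha <- fit$coefficients
    mu0 <- as.vector(covariates %*% alpha)
  } else {
    if (!all(y %in% c(0, 1))) {
      stop("dichotomous traits must be coded 0/1", call. = FALSE)
    }
    # separation is detected below; glm.fit's own warning would be redundant
    fit <- suppressWarnings(glm.fit(covariates, y, family = binomial()))
    if (!fit$converged || any(fit$fitted.values < 1e-10) ||
        any(fit$fitted.values > 1 - 1e-10)) {
      stop("logistic null fit did not converge (possible separation); ",
           "drop or recode offending covariates", call. = FALSE)
    }
    alpha <- fit$coefficients
    mu0 <- fit$fitted.values
  }
  structure(
    list(alpha_hat = alpha, mu0 = mu0, residuals = y - mu0,
         trait_type = trait_type, covariates = covariates),
    class = "trio_null_model"
  )
}

#' Center offspring genotypes at their Mendelian expectation
#'
#' Entry (i, j) is X_ij - E(X_ij | parents), the within-trio transmission
#' deviation; it is 0 whenever both parents are homozygous (no transmission
#' information) and set to 0 when any member's dosage is missing.
#'
#' @param cohort A `trio_cohort` (or any list with matrices `X`, `GF`, `GM`).
#' @param variant_ids Optional subset/order of variant columns.
#' @return List with `scores` (N x m matrix, entries in \[-1, 1\]) and
#'   `variance` (N x m conditional transmission variances, 0 where the score
#'   was zeroed).
#' @export
center_genotypes <- function(cohort, variant_ids = NULL) {
  X <- cohort$X
  GF <- cohort$GF
  GM <- cohort$GM
  if (!is.null(variant_ids)) {
    X <- X[, variant_ids, drop = FALSE]
    GF <- GF[, variant_ids, drop = FALSE]
    GM <- GM[, variant_ids, drop = FALSE]
  }
  s <- X - (GF + GM) / 2
  v <- 0.25 * ((GF == 1) + (GM == 1))
  zero <- is.na(s) | is.na(v)
  s[zero] <- 0
  v[zero] <- 0
  list(scores = s, variance = v)
}

#' Exchangeable-kernel specification
#'
#' @param weights Per-variant weights w_j.
#' @param rho Correlation of variant effects in \[0, 1\]: 0 gives the
#'   variance-component (SKAT) kernel, 1 the burden kernel.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(weights, rho = 0) {
  stopifnot(rho >= 0, rho <= 1, all(weights >= 0), all(is.finite(weights)))
  structure(list(weights = weights, rho = rho), class = "kernel_spec")
}

# W R_rho W for m variants: (1-rho) diag(w^2) + rho w w'
kernel_matrix <- function(kernel) {
  w <- kernel$weights
  (1 - kernel$rho) * diag(w^2, length(w)) + kernel$rho * tcrossprod(w)
}

#' Score-test statistic Q_rho
#'
#' Q = r' S W R_rho W S' r with r the null residuals and S the centered
#' scores. At rho = 0 this is the weighted sum of squared per-variant score
#' sums; at rho = 1 it is the square of the weighted total score (the
#' FBAT-style burden statistic).
#'
#' @param residuals Null-model residuals (length N).
#' @param scores N x m centered score matrix from [center_genotypes()].
#' @param kernel A [kernel_spec()].
#' @return Nonnegative scalar Q.
#' @export
compute_statistic <- function(residuals, scores, kernel) {
  scores <- as.matrix(scores)
  if (ncol(scores) == 0) stop("no testable variants", call. = FALSE)
  stopifnot(length(residuals) == nrow(scores),
            length(kernel$weights) == ncol(scores))
  u <- as.vector(crossprod(scores, residuals))  # per-variant score sums
  w <- kernel$weights
  q <- (1 - kernel$rho) * sum((w * u)^2) + kernel$rho * sum(w * u)^2
  max(q, 0)
}

#' Null eigenvalues of the score-test kernel
#'
#' The null law of Q_rho is the chi-square mixture sum_j lambda_j chisq_1,
#' with lambda the eigenvalues of W R_rho W V where V is the conditional
#' covariance of the summed score vector S'r given parents and trait. Two
#' estimators of V are offered: "mendelian" (default) takes transmissions at
#' distinct variants as independent given the parents, V = sum_i r_i^2 v_i
#' with v_i the diagonal per-trio transmission variances — exact for variants
#' in linkage equilibrium; "empirical" uses observed score outer products,
#' V = sum_i r_i^2 s_i s_i', and is the choice for linked variants.
#'
#' @inheritParams compute_statistic
#' @param score_variance N x m conditional variance matrix (from
#'   [center_genotypes()]); required for the "mendelian" estimator.
#' @param estimator "mendelian" or "empirical".
#' @return Nonincreasing vector of nonnegative eigenvalues; eigenvalues below
#'   1e-10 of the largest are dropped. All-zero V yields a single 0 (p = 1).
#' @export
null_eigenvalues <- function(residuals, scores, kernel,
                             score_variance = NULL,
                             estimator = c("mendelian", "empirical")) {
  estimator <- match.arg(estimator)
  scores <- as.matrix(scores)
  r2 <- residuals^2
  if (estimator == "mendelian") {
    if (is.null(score_variance)) {
      stop("score_variance is required for the mendelian estimator", call. = FALSE)
    }
    vdiag <- as.vector(crossprod(score_variance, r2))  # diag of V
    if (all(vdiag <= 0)) return(0)
    # V diagonal: eigen of V^{1/2} (W R W) V^{1/2}, symmetric psd
    sv <- sqrt(pmax(vdiag, 0))
    B <- kernel_matrix(kernel) * tcrossprod(sv)
  } else {
    V <- crossprod(scores * sqrt(r2))  # sum_i r_i^2 s_i s_i'
    if (all(abs(V) < .Machine$double.eps)) return(0)
    ev <- eigen(V, symmetric = TRUE)
    sv <- sqrt(pmax(ev$values, 0))
    Vh <- ev$vectors %*% (sv * t(ev$vectors))  # V^{1/2}
    B <- Vh %*% kernel_matrix(kernel) %*% Vh
  }
  lambda <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  keep <- lambda > 1e-10 * max(lambda)
  if (!any(keep)) return(0)
  lambda[keep]
}

#' Run one family-based region test
#'
#' Orchestrates the full test for one gene/trait/stratum cell: restrict to
#' the variant stratum, compute Beta(a, b) weights from the parental MAFs of
#' the included variants, fit the null trait model, form Q_rho, derive the
#' null eigenvalues, and compute the p-value by characteristic-function
#' inversion with moment-matching fallback.
#'
#' @param cohort A `trio_cohort`.
#' @param trait Name of the trait column in `cohort$phenotypes`.
#' @param variant_ids Optional variant subset (e.g. one gene's variants from
#'   [gene_variants()]); default all variants.
#' @param stratum "all", "rare" or "common" (parental MAF vs
#'   `maf_threshold`).
#' @param method "skat" (rho = 0), "burden" (rho = 1), or a numeric rho in
#'   \[0, 1\].
#' @param weights_beta Length-2 vector (a, b) of Beta weight parameters.
#' @param covariates Optional covariate matrix (intercept added when absent).
#' @param trait_type "continuous" or "dichotomous".
#' @param maf_threshold Rare/common MAF boundary.
#' @param estimator Conditional covariance estimator, see
#'   [null_eigenvalues()].
#' @param gene Optional gene label carried into the result.
#' @return A `trio_skat_test` object; if the stratum holds no testable
#'   variant, an untestable result with `p = NA` (not an error). Use
#'   [tidy()] for a one-row tibble.
#' @export
run_test <- function(cohort, trait, variant_ids = NULL,
                     stratum = c("all", "rare", "common"),
                     method = "skat", weights_beta = c(1, 25),
                     covariates = NULL,
                     trait_type = c("continuous", "dichotomous"),
                     maf_threshold = 0.05,
                     estimator = c("mendelian", "empirical"),
                     gene = NA_character_) {
  stratum <- match.arg(stratum)
  trait_type <- match.arg(trait_type)
  estimator <- match.arg(estimator)
  rho <- method_rho(method)

  ids <- stratum_variants(cohort, stratum, maf_threshold)
  if (!is.null(variant_ids)) ids <- intersect(variant_ids, ids)
  meta <- list(gene = gene, trait = trait, method = method_label(method),
               rho = rho, stratum = stratum, n_trios = nrow(cohort$X),
               hypothesis = "H0: tau = 0")
  if (length(ids) == 0) {
    return(new_trio_skat_test(c(meta, list(
      n_variants = 0L, statistic = NA_real_, lambda = numeric(),
      p_value = NA_real_, p_method = "untestable"))))
  }

  maf <- cohort$variants$maf[match(ids, cohort$variants$variant_id)]
  w <- beta_weights(maf, weights_beta[1], weights_beta[2])
  kern <- kernel_spec(w, rho)

  y <- cohort$phenotypes[[trait]]
  if (is.null(y)) stop("trait not found: ", trait, call. = FALSE)
  null_fit <- fit_null_model(y, covariates, trait_type)

  cs <- center_genotypes(cohort, ids)
  q <- compute_statistic(null_fit$residuals, cs$scores, kern)
  lambda <- null_eigenvalues(null_fit$residuals, cs$scores, kern,
                             score_variance = cs$variance,
                             estimator = estimator)
  pv <- pvalue_mixture(q, lambda)
  new_trio_skat_test(c(meta, list(
    n_variants = length(ids), statistic = q, lambda = lambda,
    p_value = pv$p, p_method = pv$method, weights = w, variant_ids = ids,
    scores = cs$scores, null_model = null_fit)))
}

method_rho <- function(method) {
  if (is.numeric(method)) {
    stopifnot(method >= 0, method <= 1)
    return(method)
  }
  switch(match.arg(method, c("skat", "burden")), skat = 0, burden = 1)
}

method_label <- function(method) {
  if (is.numeric(method)) sprintf("rho=%g", method) else method
}

new_trio_skat_test <- function(x) structure(x, class = "trio_skat_test")

#' @export
print.trio_skat_test <- function(x, ...) {
  cat("<trio_skat_test> ", x$method, " | trait ", x$trait,
      " | stratum ", x$stratum, "\n", sep = "")
  if (identical(x$p_method, "untestable")) {
    cat("  untestable: no variants in stratum\n")
  } else {
    cat(sprintf("  Q = %.4g on %d variants, %d trios; p = %.4g (%s)\n",
                x$statistic, x$n_variants, x$n_trios, x$p_value, x$p_method))
  }
  invisible(x)
}

#' @rdname run_test
#' @param x A `trio_skat_test`.
#' @param ... Unused.
#' @export
tidy.trio_skat_test <- function(x, ...) {
  tibble(
    gene = x$gene, trait = x$trait, method = x$method, rho = x$rho,
    stratum = x$stratum, n_variants = x$n_variants, n_trios = x$n_trios,
    statistic = x$statistic, p_value = x$p_value, p_method = x$p_method
  )
}

#' @rdname run_test
#' @export
glance.trio_skat_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_variants = x$n_variants, n_trios = x$n_trios,
         n_lambda = length(x$lambda))
}

#' Run a grid of region tests and return a tidy results table
#'
#' Maps [run_test()] over genes x traits x methods x strata and row-binds the
#' tidy one-row summaries — the shape written by the `test` CLI subcommand.
#'
#' @inheritParams run_test
#' @param regions Optional region tibble from [read_regions()]; NULL tests
#'   all variants as a single region.
#' @param traits Character vector of trait columns to test.
#' @param methods Methods to run (e.g. `c("skat", "burden")`).
#' @param strata Variant strata to run.
#' @return Tibble with one row per executed test (columns as
#'   [tidy.trio_skat_test()]).
#' @export
run_trio_tests <- function(cohort, traits, regions = NULL,
                           methods = c("skat", "burden"),
                           strata = c("rare", "common", "all"),
                           weights_beta = c(1, 25), covariates = NULL,
                           maf_threshold = 0.05,
                           estimator = c("mendelian", "empirical")) {
  estimator <- match.arg(estimator)
  genes <- if (is.null(regions)) NA_character_ else unique(regions$gene)
  grid <- tidyr::expand_grid(gene = genes, trait = traits,
                             method = methods, stratum = strata)
  purrr::pmap(grid, function(gene, trait, method, stratum) {
    ids <- if (is.na(gene)) NULL else gene_variants(regions, gene, cohort$variants)
    tidy(run_test(cohort, trait, variant_ids = ids, stratum = stratum,
                  method = method, weights_beta = weights_beta,
                  covariates = covariates, maf_threshold = maf_threshold,
                  estimator = estimator, gene = gene))
  }) |>
    purrr::list_rbind()
}

#' Plot a region test result
#'
#' Per-variant contributions to the score statistic: weighted squared score
#' sums (the rho = 0 decomposition), against parental minor-allele frequency.
#'
#' @param object A `trio_skat_test` from [run_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trio_skat_test <- function(object, ...) {
  if (identical(object$p_method, "untestable")) {
    stop("nothing to plot: untestable result", call. = FALSE)
  }
  contrib <- tibble(
    variant_id = object$variant_ids,
    weight = object$weights,
    contribution = (object$weights *
                      as.vector(crossprod(object$scores,
                                          object$null_model$residuals)))^2
  )
  ggplot2::ggplot(contrib,
                  ggplot2::aes(x = .data$variant_id, y = .data$contribution)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "weighted squared score",
                  subtitle = sprintf("%s | %s | p = %.3g", object$method,
                                     object$trait, object$p_value)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
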