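# Binomial-logit marginal regression fitted by generalized estimating
# equations with an exchangeable working correlation across the scenario
# cells of each gene, and robust (sandwich) standard errors. Used to compare
# power across scenarios while respecting that the same gene is tested many
# times.

#' Compare power across scenarios with a binomial GEE
#'
#' Fits the marginal model
#'   logit p_ij = b0 + b1 I(trait1) + b2 I(common) + b3 I(common and rare)
#'                + b4 I(SKAT) (+ b5 proportion, adjusted grid)
#' to the rejection counts y_ij ~ Binomial(n_reps, p_ij) of a
#' [run_scenarios()] power table, clustering the j scenario cells within
#' each gene i (exchangeable working correlation, sandwich covariance).
#' trait1 is the SBP stand-in and the reference cells are DBP-stand-in /
#' rare-only / burden. A joint Wald test of the two variant-stratum terms
#' (`common`, `common_and_rare`) tests for any overall power difference
#' between variant strata.
#'
#' @param power_table A `power_table` tibble (columns `gene`, `trait`,
#'   `method`, `stratum`, `n_reps`, `rejections`, optionally `proportion`).
#' @param adjusted Include the causal `proportion` covariate (requires the
#'   36-cell diluted grid).
#' @return A `trio_gee` object; see [tidy.trio_gee()] and
#'   [glance.trio_gee()].
#' @export
gee_power_comparison <- function(power_table, adjusted = FALSE) {
  tab <- dplyr::filter(as_tibble(power_table), !is.na(.data$power))
  if (dplyr::n_distinct(tab$gene) < 2) {
    stop("need at least 2 genes (clusters) for the GEE comparison",
         call. = FALSE)
  }
  X <- cbind(
    `(Intercept)` = 1,
    trait1 = as.numeric(tab$trait == "trait1"),
    common = as.numeric(tab$stratum == "common"),
    common_and_rare = as.numeric(tab$stratum == "all"),
    skat = as.numeric(tab$method == "skat")
  )
  if (adjusted) {
    if (!"proportion" %in% names(tab)) {
      stop("adjusted = TRUE needs a `proportion` column (diluted grid)",
           call. = FALSE)
    }
    X <- cbind(X, proportion = tab$proportion)
  }
  keep <- apply(X[, -1, drop = FALSE], 2, function(col) var(col) > 0)
  X <- X[, c(TRUE, keep), drop = FALSE]
  fit <- gee_binomial_fit(y = tab$rejections, size = tab$n_reps, X = X,
                          cluster = tab$gene)
  joint_terms <- intersect(c("common", "common_and_rare"), colnames(X))
  joint <- list(statistic = NA_real_, df = 0L, p.value = NA_real_)
  if (length(joint_terms) > 0) {
    b <- fit$coefficients[joint_terms]
    Vb <- fit$vcov[joint_terms, joint_terms, drop = FALSE]
    chisq <- tryCatch(drop(t(b) %*% solve(Vb, b)), error = function(e) NA_real_)
    joint <- list(statistic = chisq, df = length(b),
                  p.value = pchisq(chisq, length(b), lower.tail = FALSE))
  }
  structure(
    c(fit, list(joint_stratum_test = joint, adjusted = adjusted)),
    class = "trio_gee"
  )
}

# GEE IRLS for grouped-binomial proportions with exchangeable working
# correlation; returns robust (sandwich) covariance
gee_binomial_fit <- function(y, size, X, cluster, max_iter = 50,
                             tol = 1e-10) {
  if (all(y == 0) || all(y == size)) {
    stop("degenerate power table: every cell rejected never or always",
         call. = FALSE)
  }
  prop <- y / size
  cl <- split(seq_along(y), cluster)
  p_dim <- ncol(X)
  # independence start
  beta <- coef(glm.fit(X, prop, weights = size, family = binomial()))
  alpha <- 0
  phi <- 1
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    vfun <- mu * (1 - mu) / size          # Var(p_ij) under binomial
    pearson <- (prop - mu) / sqrt(vfun)
    n_tot <- length(y)
    # floor guards the degenerate exact-fit case (all residuals zero)
    phi <- max(sum(pearson^2) / (n_tot - p_dim), 1e-10)
    # moment estimator of the exchangeable correlation
    num <- 0
    n_pairs <- 0
    for (idx in cl) {
      e <- pearson[idx]
      if (length(e) > 1) {
        num <- num + (sum(e)^2 - sum(e^2)) / 2
        n_pairs <- n_pairs + length(e) * (length(e) - 1) / 2
      }
    }
    alpha <- if (n_pairs > p_dim) num / ((n_pairs - p_dim) * phi) else 0
    alpha <- min(max(alpha, 0), 0.95)
    B <- matrix(0, p_dim, p_dim)
    score <- numeric(p_dim)
    for (idx in cl) {
      ni <- length(idx)
      D <- X[idx, , drop = FALSE] * (mu[idx] * (1 - mu[idx]))
      A_half <- sqrt(vfun[idx])
      R <- matrix(alpha, ni, ni); diag(R) <- 1
      V <- phi * (A_half %o% A_half) * R
      Vi_D <- solve(V, D)
      B <- B + crossprod(D, Vi_D)
      score <- score + crossprod(Vi_D, prop[idx] - mu[idx])
    }
    delta <- solve(B, score)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  # sandwich covariance
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  vfun <- mu * (1 - mu) / size
  B <- matrix(0, p_dim, p_dim)
  M <- matrix(0, p_dim, p_dim)
  for (idx in cl) {
    ni <- length(idx)
    D <- X[idx, , drop = FALSE] * (mu[idx] * (1 - mu[idx]))
    A_half <- sqrt(vfun[idx])
    R <- matrix(alpha, ni, ni); diag(R) <- 1
    V <- phi * (A_half %o% A_half) * R
    Vi_D <- solve(V, D)
    B <- B + crossprod(D, Vi_D)
    ui <- crossprod(Vi_D, prop[idx] - mu[idx])
    M <- M + tcrossprod(ui)
  }
  Binv <- solve(B)
  vcov <- Binv %*% M %*% Binv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = setNames(drop(beta), colnames(X)), vcov = vcov,
       alpha = alpha, phi = phi, n_clusters = length(cl),
       n_obs = length(y), converged = max(abs(delta)) < tol)
}

#' @rdname gee_power_comparison
#' @param x A `trio_gee` object.
#' @param ... Unused.
#' @export
tidy.trio_gee <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    robust_se = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' @rdname gee_power_comparison
#' @export
glance.trio_gee <- function(x, ...) {
  tibble(
    n_clusters = x$n_clusters, n_obs = x$n_obs,
    working_correlation = x$alpha, dispersion = x$phi,
    joint_stratum_chisq = x$joint_stratum_test$statistic,
    joint_stratum_df = x$joint_stratum_test$df,
    joint_stratum_p = x$joint_stratum_test$p.value,
    converged = x$converged
  )
}

#' @export
print.trio_gee <- function(x, ...) {
  cat("<trio_gee> binomial logit GEE, exchangeable working correlation\n")
  print(tidy(x))
  cat(sprintf("joint variant-stratum Wald test: chisq = %.3f (df %d), p = %.4g\n",
              x$joint_stratum_test$statistic, x$joint_stratum_test$df,
              x$joint_stratum_test$p.value))
  invisible(x)
}
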