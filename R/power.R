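# The simulation study design: a scenario grid (trait x method x variant
# stratum, optionally x causal-signal proportion), replicate-based empirical
# power and type-I error, and signal dilution by adding noncausal variants.

#' The trait x method x stratum scenario grid
#'
#' The 12-cell cross of trait (trait1/trait2, SBP/DBP stand-ins) x method
#' (skat/burden) x variant stratum (rare/common/all); crossing in causal
#' proportions (e.g. 0.10, 0.25, 0.50) gives the 36-cell adjusted grid.
#'
#' @param proportions Optional numeric vector of causal-variant proportions.
#' @param traits,methods,strata Factors of the grid.
#' @return Tibble with columns `trait`, `method`, `stratum` and, when
#'   `proportions` is given, `proportion`.
#' @export
scenario_grid <- function(proportions = NULL,
                          traits = c("trait1", "trait2"),
                          methods = c("skat", "burden"),
                          strata = c("rare", "common", "all")) {
  grid <- tidyr::expand_grid(trait = traits, method = methods, stratum = strata)
  if (!is.null(proportions)) {
    grid <- tidyr::expand_grid(grid, proportion = proportions)
  }
  grid
}

#' Dilute a gene's causal signal with noncausal variants
#'
#' Keeps every causal variant and adds k = round(n_causal (1 - pi) / pi)
#' noncausal variants sampled without replacement, so the causal proportion
#' of the returned set is as close as possible to `target_proportion`.
#'
#' @param truth Truth tibble from [generate_cohort()] (columns `variant_id`,
#'   `causal`).
#' @param target_proportion Desired causal proportion pi in (0, 1\].
#' @param seed Integer seed for the noncausal draw.
#' @return Character vector of variant ids. If the gene lacks enough
#'   noncausal variants, all of them are used, with a warning.
#' @export
dilute_signal <- function(truth, target_proportion, seed) {
  stopifnot(target_proportion > 0, target_proportion <= 1)
  causal <- truth$variant_id[truth$causal]
  noncausal <- truth$variant_id[!truth$causal]
  if (length(causal) == 0) stop("gene has no causal variants", call. = FALSE)
  k <- round(length(causal) * (1 - target_proportion) / target_proportion)
  if (k > length(noncausal)) {
    warning("only ", length(noncausal), " noncausal variants available (",
            k, " requested); using all", call. = FALSE)
    k <- length(noncausal)
  }
  picked <- withr::with_seed(as.integer(seed),
                             sample(noncausal, k, replace = FALSE))
  c(causal, picked)
}

# genes (list entries from generate_cohort) eligible for the dilution study:
# at least one causal rare and one causal common variant
has_causal_both_strata <- function(truth, maf_threshold = 0.05) {
  c_maf <- truth$maf[truth$causal]
  any(c_maf > 0 & c_maf <= maf_threshold) && any(c_maf > maf_threshold)
}

#' Empirical power over a scenario grid
#'
#' Simulates `n_genes` independent gene cohorts from `config`, then for each
#' replicate redraws phenotypes (genotypes stay fixed across replicates, the
#' design of a simulation study whose replicates share genotypes; set
#' `regenerate = "cohort"` to redraw genotypes too), runs every grid cell
#' through [run_test()], and counts rejections at level `alpha`.
#'
#' When the grid carries a `proportion` column, the variant set of each
#' (gene, proportion) cell is fixed once by [dilute_signal()] and only genes
#' with at least one causal rare and one causal common variant are used.
#'
#' @param config A [sim_config()] describing one gene (its seed is ignored;
#'   per-gene seeds derive from `seed`).
#' @param grid Tibble from [scenario_grid()].
#' @param n_genes Number of independent gene cohorts.
#' @param n_reps Replicates per gene.
#' @param alpha Rejection level (default 0.05).
#' @param seed Master seed; every random draw derives from it.
#' @param regenerate "phenotypes" (default) or "cohort".
#' @param weights_beta Beta weight parameters passed to [run_test()].
#' @param maf_threshold Rare/common boundary.
#' @return A `power_table` tibble: `gene`, `trait`, `method`, `stratum`,
#'   (`proportion`,) `n_reps`, `rejections`, `power`. Untestable cells
#'   (empty stratum in every replicate) have `NA` power.
#' @export
run_scenarios <- function(config, grid = scenario_grid(), n_genes = 1,
                          n_reps = 200, alpha = 0.05, seed = 1,
                          regenerate = c("phenotypes", "cohort"),
                          weights_beta = c(1, 25), maf_threshold = 0.05) {
  regenerate <- match.arg(regenerate)
  diluted <- "proportion" %in% names(grid)
  if (diluted && regenerate == "cohort") {
    stop("the dilution design fixes causal sets per gene and so requires ",
         'regenerate = "phenotypes"', call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_genes * (2 + n_reps))
  seed_mat <- matrix(seeds, nrow = n_genes)

  gene_tables <- purrr::map(seq_len(n_genes), function(g) {
    gcfg <- config
    gcfg$seed <- seed_mat[g, 1]
    sim <- generate_cohort(gcfg)
    if (diluted && !has_causal_both_strata(sim$truth, maf_threshold)) {
      return(NULL)
    }
    subsets <- NULL
    if (diluted) {
      props <- unique(grid$proportion)
      subsets <- setNames(
        purrr::map(props, ~ dilute_signal(sim$truth, .x, seed_mat[g, 2])),
        as.character(props)
      )
    }
    rejections <- matrix(0L, nrow(grid), 1)
    tested <- rep(0L, nrow(grid))
    for (rep_i in seq_len(n_reps)) {
      rep_seed <- seed_mat[g, 2 + rep_i]
      if (regenerate == "cohort") {
        rcfg <- config
        rcfg$seed <- rep_seed
        rsim <- generate_cohort(rcfg)
        cohort <- rsim$cohort
      } else {
        cohort <- regenerate_phenotypes(sim$cohort, sim$truth, config,
                                        rep_seed, sim$subpop)
      }
      for (cell in seq_len(nrow(grid))) {
        ids <- if (diluted) subsets[[as.character(grid$proportion[cell])]] else NULL
        res <- run_test(cohort, trait = grid$trait[cell], variant_ids = ids,
                        stratum = grid$stratum[cell],
                        method = grid$method[cell],
                        weights_beta = weights_beta,
                        maf_threshold = maf_threshold,
                        gene = sprintf("gene%d", g))
        if (!is.na(res$p_value)) {
          tested[cell] <- tested[cell] + 1L
          rejections[cell] <- rejections[cell] + (res$p_value <= alpha)
        }
      }
    }
    out <- grid
    out$gene <- sprintf("gene%d", g)
    out$n_reps <- tested
    out$rejections <- as.integer(rejections)
    out$power <- ifelse(tested > 0, rejections / tested, NA_real_)
    out
  })
  out <- purrr::list_rbind(purrr::compact(gene_tables))
  if (nrow(out) == 0) {
    stop("no gene met the dilution eligibility rule (>=1 causal rare and ",
         ">=1 causal common variant)", call. = FALSE)
  }
  out <- dplyr::relocate(out, "gene")
  structure(out, class = c("power_table", class(out)))
}

#' Empirical type-I error on the null trait
#'
#' Runs the scenario machinery on the genotype-independent null trait `q1`:
#' the rejection rate at level `alpha` estimates the empirical type-I error
#' of each method. By default every replicate draws a fresh cohort.
#'
#' @inheritParams run_scenarios
#' @param methods Methods to calibrate.
#' @param stratum Variant stratum used for the null tests.
#' @return Tibble `method`, `n_reps`, `rejections`, `rate`, `se` (binomial
#'   standard error at the nominal level).
#' @export
estimate_type1_error <- function(config, n_reps = 2000, alpha = 0.05,
                                 seed = 1, methods = c("skat", "burden"),
                                 stratum = "all",
                                 regenerate = c("cohort", "phenotypes"),
                                 weights_beta = c(1, 25)) {
  regenerate <- match.arg(regenerate)
  grid <- scenario_grid(traits = "q1", methods = methods, strata = stratum)
  tab <- run_scenarios(config, grid = grid, n_genes = 1, n_reps = n_reps,
                       alpha = alpha, seed = seed, regenerate = regenerate,
                       weights_beta = weights_beta)
  tibble(
    method = tab$method,
    n_reps = tab$n_reps,
    rejections = tab$rejections,
    rate = tab$power,
    se = sqrt(alpha * (1 - alpha) / tab$n_reps)
  )
}

# deterministic stream of sub-seeds below 2^31
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Plot a power table
#'
#' Power by gene and variant stratum, faceted by trait, coloured by method;
#' diluted tables facet on the causal proportion as well.
#'
#' @param object A `power_table` from [run_scenarios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_table <- function(object, ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$stratum, y = .data$power,
                 fill = .data$method)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "variant stratum", y = "empirical power",
                  fill = "method") +
    ggplot2::ylim(0, 1)
  if ("proportion" %in% names(object)) {
    p + ggplot2::facet_grid(trait ~ proportion,
                            labeller = ggplot2::label_both)
  } else {
    p + ggplot2::facet_grid(trait ~ gene)
  }
}
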