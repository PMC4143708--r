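# Synthetic trio cohorts with known truth. Parents are drawn under
# Hardy-Weinberg equilibrium from a configurable MAF spectrum (a 1/f
# neutral-spectrum caricature for rare variants, uniform for common ones),
# offspring follow Mendelian transmission, and two correlated quantitative
# traits carry a configurable causal architecture next to a pure-noise null
# trait. An optional two-subpopulation mode (Balding-Nichols divergence plus
# a trait mean offset) creates the confounding that population-based tests
# are vulnerable to.

#' Simulation configuration
#'
#' Defaults emulate a blood-pressure-style trio study: 93 trios, 30 variants
#' per gene of which 80% are rare (MAF <= 0.05), two highly correlated
#' traits (`trait1`/`trait2`, SBP/DBP stand-ins; trait2 carries 0.8x the
#' genetic effects with residual correlation 0.6) and a genotype-independent
#' null trait `q1`.
#'
#' @param n_trios Number of trios N.
#' @param n_variants Number of variants m in the simulated region.
#' @param proportion_rare Fraction of variants drawn from the rare spectrum.
#' @param maf_min Lower MAF bound; default 1/(4 N), the rarest frequency at
#'   which a variant is likely polymorphic among 2N parents.
#' @param maf_rare_max Rare-spectrum upper bound (default 0.05).
#' @param maf_common_max Common-spectrum upper bound (default 0.5).
#' @param causal_fraction Fraction of variants with nonzero effect on
#'   trait1/trait2.
#' @param effect_model "log_maf" gives |beta_j| = effect_scale * |log10 f_j|
#'   (rarer variants have larger effects); "constant" gives
#'   |beta_j| = effect_scale.
#' @param effect_scale Effect magnitude scale c; 0 gives a fully null model.
#' @param direction_mix Probability a causal effect is positive (1 =
#'   same-direction burden-favourable architecture, 0.5 = balanced mixed
#'   signs, SKAT-favourable).
#' @param trait_share Multiplier applied to trait1's effects for trait2.
#' @param resid_cor Residual correlation between trait1 and trait2.
#' @param trait_sd Residual standard deviation of each trait.
#' @param stratification NULL, or a list with `fst` (Balding-Nichols
#'   divergence of the two subpopulations), `mean_offset` (added to both
#'   traits in subpopulation 2) and optionally `prob` (P(subpop 2), default
#'   0.5). Both parents of a trio share a subpopulation.
#' @param seed Integer master seed (required for [generate_cohort()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trios = 93, n_variants = 30, proportion_rare = 0.8,
                       maf_min = 1 / (4 * n_trios), maf_rare_max = 0.05,
                       maf_common_max = 0.5, causal_fraction = 0.2,
                       effect_model = c("log_maf", "constant"),
                       effect_scale = 0, direction_mix = 1,
                       trait_share = 0.8, resid_cor = 0.6, trait_sd = 1,
                       stratification = NULL, seed = NULL) {
  effect_model <- match.arg(effect_model)
  stopifnot(
    n_trios >= 1, n_variants >= 1,
    proportion_rare >= 0, proportion_rare <= 1,
    maf_min > 0, maf_min < maf_rare_max, maf_rare_max <= maf_common_max,
    maf_common_max <= 0.5,
    causal_fraction >= 0, causal_fraction <= 1,
    direction_mix >= 0, direction_mix <= 1,
    resid_cor > -1, resid_cor < 1, trait_sd > 0
  )
  if (!is.null(stratification)) {
    stopifnot(is.list(stratification), stratification$fst > 0,
              stratification$fst < 1)
    stratification$prob <- stratification$prob %||% 0.5
    stratification$mean_offset <- stratification$mean_offset %||% 0
  }
  structure(
    list(n_trios = n_trios, n_variants = n_variants,
         proportion_rare = proportion_rare, maf_min = maf_min,
         maf_rare_max = maf_rare_max, maf_common_max = maf_common_max,
         causal_fraction = causal_fraction, effect_model = effect_model,
         effect_scale = effect_scale, direction_mix = direction_mix,
         trait_share = trait_share, resid_cor = resid_cor,
         trait_sd = trait_sd, stratification = stratification,
         seed = seed),
    class = "sim_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a minor-allele frequency spectrum
#'
#' Rare variants get density proportional to 1/f on (maf_min, maf_rare_max];
#' common variants are uniform on (maf_rare_max, maf_common_max].
#'
#' @param config A [sim_config()].
#' @return Numeric vector of length `n_variants` in (0, 0.5\].
#' @export
simulate_mafs <- function(config) {
  m <- config$n_variants
  rare <- runif(m) < config$proportion_rare
  f <- numeric(m)
  # inverse-CDF draw from density 1/f on (maf_min, maf_rare_max]
  u <- runif(sum(rare))
  f[rare] <- config$maf_min * (config$maf_rare_max / config$maf_min)^u
  f[!rare] <- runif(sum(!rare), config$maf_rare_max, config$maf_common_max)
  f
}

#' Draw parental genotypes under Hardy-Weinberg equilibrium
#'
#' Each parent's dosage at variant j is Binomial(2, f_j), independently. With
#' stratification, each trio's parents share a subpopulation whose MAFs are
#' Balding-Nichols draws around the base spectrum.
#'
#' @param mafs Base MAF vector (length m).
#' @param config A [sim_config()].
#' @return List with `GF`, `GM` (N x m dosage matrices) and `subpop`
#'   (per-trio labels 1/2, all 1 without stratification).
#' @export
simulate_parents <- function(mafs, config) {
  N <- config$n_trios
  m <- length(mafs)
  strat <- config$stratification
  if (is.null(strat)) {
    subpop <- rep(1L, N)
    fmat <- matrix(mafs, N, m, byrow = TRUE)
  } else {
    subpop <- 1L + (runif(N) < strat$prob)
    # Balding-Nichols: subpopulation frequencies around the ancestral MAF
    a <- mafs * (1 - strat$fst) / strat$fst
    b <- (1 - mafs) * (1 - strat$fst) / strat$fst
    f1 <- stats::rbeta(m, a, b)
    f2 <- stats::rbeta(m, a, b)
    fmat <- rbind(f1, f2)[subpop, , drop = FALSE]
  }
  GF <- matrix(rbinom(N * m, 2, as.vector(fmat)), N, m)
  GM <- matrix(rbinom(N * m, 2, as.vector(fmat)), N, m)
  list(GF = GF, GM = GM, subpop = subpop)
}

#' Draw offspring genotypes by Mendelian transmission
#'
#' Each parent transmits one allele; heterozygous parents transmit the coded
#' allele with probability 1/2. Offspring are Mendelian-consistent with
#' their parents by construction.
#'
#' @param GF,GM Parental N x m dosage matrices.
#' @return N x m offspring dosage matrix.
#' @export
simulate_offspring <- function(GF, GM) {
  stopifnot(identical(dim(GF), dim(GM)))
  n <- length(GF)
  from_f <- rbinom(n, 1, as.vector(GF) / 2)
  from_m <- rbinom(n, 1, as.vector(GM) / 2)
  matrix(from_f + from_m, nrow(GF), ncol(GF))
}

#' Draw the causal architecture (truth) for a simulated region
#'
#' @param mafs MAF vector.
#' @param config A [sim_config()].
#' @return Tibble `variant_id`, `maf`, `causal`, `beta_trait1`,
#'   `beta_trait2` (all betas 0 for the null trait).
#' @keywords internal
simulate_truth <- function(mafs, config) {
  m <- length(mafs)
  n_causal <- round(config$causal_fraction * m)
  causal <- rep(FALSE, m)
  causal[sample.int(m, n_causal)] <- TRUE
  mag <- switch(config$effect_model,
    log_maf = config$effect_scale * abs(log10(mafs)),
    constant = rep(config$effect_scale, m)
  )
  # direction_mix is the exact proportion of positive-sign causal effects;
  # which causal variants get the negative signs is random
  sign <- rep(1, m)
  n_neg <- round((1 - config$direction_mix) * n_causal)
  if (n_neg > 0) {
    neg <- sample(which(causal), n_neg)
    sign[neg] <- -1
  }
  beta1 <- ifelse(causal, sign * mag, 0)
  tibble(
    variant_id = sprintf("v%0*d", nchar(m), seq_len(m)),
    maf = mafs, causal = causal,
    beta_trait1 = beta1,
    beta_trait2 = config$trait_share * beta1
  )
}

#' Simulate the phenotype table for given offspring genotypes
#'
#' trait1 = X beta1 + e1 and trait2 = X beta2 + e2 with (e1, e2) bivariate
#' normal (correlation `resid_cor`, sd `trait_sd`); `q1` is independent
#' noise. Under stratification, `mean_offset` is added to trait1 and trait2
#' (not q1's genetic null — q1 stays genotype-independent but also receives
#' the offset so that confounding affects every non-null analysis choice).
#'
#' @param X N x m offspring dosage matrix.
#' @param truth Truth tibble from the generator.
#' @param config A [sim_config()].
#' @param subpop Per-trio subpopulation labels (1/2).
#' @return Tibble with columns `trait1`, `trait2`, `q1`.
#' @export
simulate_traits <- function(X, truth, config, subpop = NULL) {
  N <- nrow(X)
  g1 <- as.vector(X %*% truth$beta_trait1)
  g2 <- as.vector(X %*% truth$beta_trait2)
  e1 <- rnorm(N, 0, config$trait_sd)
  e2 <- config$resid_cor * e1 +
    sqrt(1 - config$resid_cor^2) * rnorm(N, 0, config$trait_sd)
  offset <- 0
  if (!is.null(config$stratification) && !is.null(subpop)) {
    offset <- config$stratification$mean_offset * (subpop == 2L)
  }
  tibble(
    trait1 = g1 + e1 + offset,
    trait2 = g2 + e2 + offset,
    q1 = rnorm(N, 0, config$trait_sd) + offset
  )
}

#' Generate a complete synthetic trio cohort
#'
#' Deterministic given `config$seed`: draws the MAF spectrum, the causal
#' architecture, parental genotypes under HWE, offspring by Mendelian
#' transmission, and the three traits, then assembles a [trio_cohort()]
#' (IDs F_i / M_i / O_i).
#'
#' @param config A [sim_config()] with a non-NULL seed.
#' @return List with `cohort` (a `trio_cohort`) and `truth` (tibble, plus a
#'   `subpop` column).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) stop("sim_config needs a seed", call. = FALSE)
  withr::with_seed(as.integer(config$seed), {
    mafs <- simulate_mafs(config)
    truth <- simulate_truth(mafs, config)
    par <- simulate_parents(mafs, config)
    X <- simulate_offspring(par$GF, par$GM)
    pheno <- simulate_traits(X, truth, config, par$subpop)
  })
  cohort <- assemble_sim_cohort(par, X, truth, pheno)
  truth$subpop_fraction <- mean(par$subpop == 2L)
  list(cohort = cohort, truth = truth, subpop = par$subpop)
}

assemble_sim_cohort <- function(par, X, truth, pheno) {
  N <- nrow(X)
  trios <- tibble(
    family_id = sprintf("FAM%d", seq_len(N)),
    father_id = sprintf("F_%d", seq_len(N)),
    mother_id = sprintf("M_%d", seq_len(N)),
    offspring_id = sprintf("O_%d", seq_len(N)),
    trio = seq_len(N)
  )
  dosage <- rbind(par$GF, par$GM, X)
  rownames(dosage) <- c(trios$father_id, trios$mother_id, trios$offspring_id)
  variants <- tibble(
    variant_id = truth$variant_id, chrom = "1",
    pos = seq_len(ncol(X)) * 1000L,
    ref = "A", alt = "C"
  )
  trio_cohort(trios, list(dosage = dosage, variants = variants), pheno)
}

#' Redraw phenotypes for an existing simulated cohort
#'
#' Keeps genotypes (and hence MAFs, weights, kernels) fixed and redraws only
#' the trait noise — the replicate structure of a simulation study whose
#' replicates share genotypes.
#'
#' @param cohort A simulated `trio_cohort`.
#' @param truth Truth tibble from [generate_cohort()].
#' @param config The originating [sim_config()].
#' @param seed Integer seed for the redraw.
#' @param subpop Per-trio subpopulation labels from [generate_cohort()].
#' @return The cohort with a fresh `phenotypes` table.
#' @export
regenerate_phenotypes <- function(cohort, truth, config, seed, subpop = NULL) {
  withr::with_seed(as.integer(seed), {
    cohort$phenotypes <- simulate_traits(cohort$X, truth, config, subpop)
  })
  cohort
}
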