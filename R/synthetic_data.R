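#' Simulation scenario for genotype/phenotype generation
#'
#' Describes a synthetic unrelated-sample study of one genomic region:
#' sample size, a MAF spectrum, a set of causal variants with effect sizes
#' in trait-SD units, Gaussian noise, and an optional genotype missingness
#' rate. Defaults emulate a single-gene sequencing panel: n = 1851
#' individuals and p = 85 variants whose MAFs form a deterministic
#' log-spaced grid over `[3e-4, 0.35]`, so extreme-rare singleton-prone
#' sites and common polymorphisms are both present. The MAF grid does not
#' depend on the seed: scenarios differing only in seed share identical
#' spectrum parameters.
#'
#' @param n individuals.
#' @param p variants (ignored when `maf_spectrum` is given).
#' @param maf_spectrum per-variant population MAFs in `(0, 0.5]`.
#' @param causal_index integer indices of causal variants (default none).
#' @param effect_sizes per-causal-variant effects, units of `noise_sd`.
#' @param intercept trait intercept.
#' @param noise_sd residual SD (> 0).
#' @param missing_rate per-entry genotype missingness probability.
#' @param seed integer seed; genotypes use `seed`, phenotype noise
#'   `seed + 1`.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n = 1851L, p = 85L, maf_spectrum = NULL,
                                causal_index = integer(0),
                                effect_sizes = numeric(0),
                                intercept = 0, noise_sd = 1,
                                missing_rate = 0, seed = 1L) {
  if (is.null(maf_spectrum))
    maf_spectrum <- exp(seq(log(3e-4), log(0.35), length.out = p))
  p <- length(maf_spectrum)
  stopifnot(all(maf_spectrum > 0), all(maf_spectrum <= 0.5),
            noise_sd > 0, missing_rate >= 0, missing_rate < 1,
            length(causal_index) == length(effect_sizes),
            all(causal_index %in% seq_len(p)))
  structure(list(n = as.integer(n), p = p, maf_spectrum = maf_spectrum,
                 causal_index = as.integer(causal_index),
                 effect_sizes = effect_sizes, intercept = intercept,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each dosage is an independent `Binomial(2, maf_j)` draw (no linkage
#' disequilibrium), matching the additive-coding assumption of the model;
#' missing entries are masked at `missing_rate`. Variant IDs follow the
#' `<chrom>_<pos>` convention (`"1_<pos>"`, positions 1 kb apart). The
#' complete pre-masking dosage matrix is kept in attribute
#' `"complete_dosages"` so phenotype simulation is exact under missingness.
#'
#' @param scenario a [simulation_scenario()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n; p <- scenario$p
  X <- vapply(scenario$maf_spectrum,
              function(m) stats::rbinom(n, 2L, m), numeric(n))
  complete <- X
  if (scenario$missing_rate > 0)
    X[matrix(stats::runif(n * p) < scenario$missing_rate, n, p)] <- NA
  ids <- sprintf("1_%d", 1000000L + 1000L * seq_len(p))
  gm <- genotype_matrix(X, variant_ids = ids)
  attr(gm, "complete_dosages") <- complete
  gm
}

#' Simulate a quantitative phenotype from genotypes
#'
#' `Y_i = intercept + sum_j beta_j X_ij + e_i` with iid Gaussian noise
#' `e_i ~ N(0, noise_sd^2)`, summing over the scenario's causal variants.
#' Noise is seeded at `scenario$seed + 1`, independently of the genotype
#' draw, so changing an effect size on a fixed seed shifts carriers'
#' phenotypes by exactly the effect times the dosage.
#'
#' @param genotypes a [simulate_genotypes()] result (its complete dosage
#'   attribute is used when present, so masked entries still contribute).
#' @param scenario the same [simulation_scenario()].
#' @return a [phenotype_vector()].
#' @export
simulate_phenotype <- function(genotypes, scenario) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(scenario, "simulation_scenario"))
  X <- attr(genotypes, "complete_dosages")
  if (is.null(X)) {
    X <- genotypes$values
    X[is.na(X)] <- 0
  }
  set.seed(scenario$seed + 1L)
  eta <- rep(scenario$intercept, scenario$n)
  if (length(scenario$causal_index) > 0L)
    eta <- eta + drop(X[, scenario$causal_index, drop = FALSE] %*%
                        scenario$effect_sizes)
  phenotype_vector(eta + stats::rnorm(scenario$n, 0, scenario$noise_sd),
                   sample_ids = genotypes$sample_ids)
}

#' Simulate a full dataset
#'
#' @param scenario a [simulation_scenario()].
#' @return list with `genotypes`, `phenotype`, `scenario`.
#' @export
simulate_dataset <- function(scenario) {
  genotypes <- simulate_genotypes(scenario)
  list(genotypes = genotypes,
       phenotype = simulate_phenotype(genotypes, scenario),
       scenario = scenario)
}

#' Effect-free replicate for type-I calibration
#'
#' Strips all causal effects from a scenario (keeping its sample size, MAF
#' spectrum, noise and missingness) and simulates genotypes and a purely
#' noise-driven phenotype under the given seed.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed optional replacement seed.
#' @return list with `genotypes`, `phenotype`, `scenario` (causal set empty).
#' @export
make_null_replicate <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  scenario$causal_index <- integer(0)
  scenario$effect_sizes <- numeric(0)
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  simulate_dataset(scenario)
}
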