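# Small simulated datasets used across tests. All seeded; built in code,
# no stored fixtures.

# filtered dataset + grouping with a strong common causal variant
tiny_assoc_data <- function(n = 200, seed = 11, beta = 0.8,
                            threshold = 0.05) {
  sc <- simulation_scenario(
    n = n, maf_spectrum = c(0.25, 0.1, 0.04, 0.02, 0.01),
    causal_index = 1L, effect_sizes = beta, seed = seed)
  d <- simulate_dataset(sc)
  fl <- filter_data(d$genotypes, d$phenotype)
  list(genotypes = fl$genotypes, phenotype = fl$phenotype,
       grouping = partition_by_maf(fl$genotypes, threshold),
       scenario = sc)
}

# short sampler settings for module-level chain tests
fast_config <- function(seed = 1, ...) {
  sampler_config(burn_in = 500L, n_keep = 1000L, thin = 2L, seed = seed, ...)
}

# genotype_matrix with prescribed MAFs (partitioning logic only looks at
# maf/region/positions, so the dosages are immaterial)
gm_with_mafs <- function(mafs, region = NULL) {
  p <- length(mafs)
  gm <- genotype_matrix(matrix(rep(c(0, 1), length.out = 4 * p), 4, p))
  gm$maf <- mafs
  if (!is.null(region)) gm$region <- region
  gm
}

# independent brute-force posterior: double loop over all models, lm() fits,
# Gaussian log-density at the MLE -- deliberately naive, shares no code with
# the package's scorer
brute_force_mpp <- function(phenotype, genotypes, grouping, pip) {
  y <- phenotype$values
  n <- length(y)
  p <- genotypes$p
  gammas <- as.matrix(expand.grid(rep(list(0:1), p)))
  logs <- apply(gammas, 1, function(g) {
    act <- sort(unique(grouping$group_of[g == 1]))
    if (length(act) == 0L) {
      s2 <- mean((y - mean(y))^2)
      ll <- sum(stats::dnorm(y, mean(y), sqrt(s2), log = TRUE))
    } else {
      D <- sapply(act, function(gr) {
        cols <- which(g == 1 & grouping$group_of == gr)
        rowSums(genotypes$values[, cols, drop = FALSE])
      })
      fit <- stats::lm(y ~ D)
      s2 <- max(mean(stats::residuals(fit)^2),
                1e-12 * mean((y - mean(y))^2))
      ll <- sum(stats::dnorm(y, stats::fitted(fit), sqrt(s2), log = TRUE))
    }
    sum(g) * log(pip) + (p - sum(g)) * log(1 - pip) + ll
  })
  w <- exp(logs - max(logs))
  post <- w / sum(w)
  drop(crossprod(gammas, post))
}
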