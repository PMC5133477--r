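test_that("log_prior matches the Bernoulli closed form", {
  expect_equal(log_prior(c(0, 0, 0), 0.1), 3 * log(0.9))
  expect_equal(log_prior(c(1, 0, 1), 0.5), 3 * log(0.5))  # uniform over M
  expect_equal(log_prior(c(1, 1, 0, 0, 0), 0.1),
               2 * log(0.1) + 3 * log(0.9))
  expect_error(log_prior(c(0, 1), 1), "strictly")
  expect_error(log_prior(c(0, 1), 0), "strictly")
  expect_error(log_prior(c(0, 2), 0.1), "binary")
})

test_that("plug-in likelihood equals the Gaussian density at the MLE", {
  # intercept-only: independent oracle is the normal log-density itself
  y <- c(1, 2, 3)
  fit <- plug_in_log_likelihood(y)
  expect_equal(fit$beta0, 2)
  expect_equal(fit$sigma2, 2 / 3)
  expect_equal(fit$log_lik, sum(dnorm(y, 2, sqrt(2 / 3), log = TRUE)))

  set.seed(8)
  for (i in 1:5) {
    n <- 30
    D <- matrix(rbinom(n * 3, 2, 0.3), n)
    y <- rnorm(n, 0.5 + D %*% c(1, 0, -0.5))
    f <- plug_in_log_likelihood(y, D)
    ols <- lm(y ~ D)
    expect_equal(f$beta0, unname(coef(ols)[1]))
    expect_equal(f$beta, unname(coef(ols)[-1]))
    s2 <- mean(residuals(ols)^2)
    expect_equal(f$sigma2, s2)
    expect_equal(f$log_lik, sum(dnorm(y, fitted(ols), sqrt(s2), log = TRUE)))
  }
})

test_that("perfect and near-perfect fits hit the variance floor, finitely", {
  D <- matrix(c(0, 1, 2), 3, 1)
  y <- c(0.1, 1.1, 2.1)  # exact interpolation by intercept + column
  f <- plug_in_log_likelihood(y, D)
  expect_equal(f$beta0, 0.1)
  expect_equal(f$beta, 1)
  expect_equal(f$sigma2, 1e-12 * mean((y - mean(y))^2))
  expect_true(is.finite(f$log_lik))
  expect_error(plug_in_log_likelihood(c(1)), "at least 2")
  expect_error(plug_in_log_likelihood(c(1, NA)), "finite")
})

test_that("rank-deficient designs keep the same RSS as a full-rank subset", {
  set.seed(12)
  n <- 40
  x <- rbinom(n, 2, 0.3)
  y <- rnorm(n, x)
  f1 <- plug_in_log_likelihood(y, cbind(x))
  f2 <- plug_in_log_likelihood(y, cbind(x, x))  # duplicated column
  expect_equal(f2$log_lik, f1$log_lik)
  expect_equal(f2$rss, f1$rss)
})

test_that("adding a design column never decreases the plug-in likelihood", {
  set.seed(13)
  for (i in 1:10) {
    n <- 25
    D <- matrix(rbinom(n * 4, 2, 0.2), n)
    y <- rnorm(n)
    lls <- vapply(0:4, function(m)
      plug_in_log_likelihood(y, D[, seq_len(m), drop = FALSE])$log_lik,
      numeric(1))
    expect_true(all(diff(lls) >= -1e-9))
  }
})

test_that("score_state composes prior and likelihood exactly", {
  dat <- tiny_assoc_data(n = 80)
  p <- dat$genotypes$p
  st0 <- score_state(dat$phenotype, dat$genotypes, dat$grouping,
                     rep(0L, p), 0.1)
  expect_equal(st0$log_prior, p * log(0.9))
  expect_equal(st0$log_lik,
               plug_in_log_likelihood(dat$phenotype)$log_lik)
  expect_equal(st0$log_score, st0$log_prior + st0$log_lik)

  set.seed(3)
  for (i in 1:5) {
    g <- rbinom(p, 1, 0.4)
    st <- score_state(dat$phenotype, dat$genotypes, dat$grouping, g, 0.1)
    D <- build_risk_design(dat$genotypes, dat$grouping, g)
    expect_equal(st$log_score,
                 log_prior(g, 0.1) +
                   plug_in_log_likelihood(dat$phenotype, D)$log_lik)
  }
})

test_that("score is invariant to variant order within a rare group", {
  dat <- tiny_assoc_data(n = 250)
  gr <- dat$grouping
  rare <- which(gr$group_is_rare[gr$group_of])
  expect_gte(length(rare), 2)
  g1 <- integer(dat$genotypes$p); g1[rare[1]] <- 1L; g1[rare[2]] <- 1L
  # swap the two rare columns in the genotype matrix: same risk index
  gm2 <- dat$genotypes
  gm2$values[, c(rare[1], rare[2])] <- gm2$values[, c(rare[2], rare[1])]
  s1 <- score_state(dat$phenotype, dat$genotypes, gr, g1, 0.1)
  s2 <- score_state(dat$phenotype, gm2, gr, g1, 0.1)
  expect_equal(s1$log_score, s2$log_score)
})

test_that("fast chain scorer agrees with score_state everywhere", {
  dat <- tiny_assoc_data(n = 120)
  p <- dat$genotypes$p
  scorer <- rvbvs:::.make_scorer(dat$phenotype, dat$genotypes,
                                 dat$grouping, 0.1)
  set.seed(31)
  gammas <- rbind(rep(0L, p), rep(1L, p),
                  matrix(rbinom(8 * p, 1, 0.5), 8))
  for (i in seq_len(nrow(gammas))) {
    g <- gammas[i, ]
    expect_equal(scorer(g),
                 score_state(dat$phenotype, dat$genotypes, dat$grouping,
                             g, 0.1)$log_score,
                 tolerance = 1e-8)
  }
})

test_that("exact enumeration matches an independent brute-force oracle", {
  sc <- simulation_scenario(
    n = 90, maf_spectrum = c(0.3, 0.15, 0.04, 0.03, 0.02, 0.015, 0.01, 0.01),
    causal_index = c(1L, 3L), effect_sizes = c(0.5, 0.8), seed = 17)
  d <- simulate_dataset(sc)
  fl <- filter_data(d$genotypes, d$phenotype, min_minor_allele_count = 0)
  gr <- partition_by_maf(fl$genotypes, 0.05)
  ex <- enumerate_exact_posterior(fl$phenotype, fl$genotypes, gr, 0.1)
  expect_equal(sum(ex$posterior), 1, tolerance = 1e-10)
  oracle <- brute_force_mpp(fl$phenotype, fl$genotypes, gr, 0.1)
  expect_equal(unname(ex$mpp), unname(oracle), tolerance = 1e-10)
  expect_true(all(ex$mpp >= 0 & ex$mpp <= 1))
})

test_that("single-variant posterior odds follow the two-state closed form", {
  set.seed(19)
  x <- rbinom(60, 2, 0.25)
  y <- rnorm(60, 0.4 * x)
  gm <- genotype_matrix(cbind(v1 = x), orient_minor = FALSE)
  ph <- phenotype_vector(y)
  gr <- partition_by_maf(gm, 0.05)
  ex <- enumerate_exact_posterior(ph, gm, gr, 0.1)
  dll <- plug_in_log_likelihood(ph, cbind(x))$log_lik -
    plug_in_log_likelihood(ph)$log_lik
  odds <- exp(dll) * 0.1 / 0.9
  expect_equal(unname(ex$mpp), odds / (1 + odds), tolerance = 1e-10)
  expect_error(enumerate_exact_posterior(ph, gm, gr, 0.1, max_p = 0),
               "max_p")
})

test_that("exact MPPs move continuously with the prior inclusion probability", {
  dat <- tiny_assoc_data(n = 70)
  ex1 <- enumerate_exact_posterior(dat$phenotype, dat$genotypes,
                                   dat$grouping, 0.10)
  ex2 <- enumerate_exact_posterior(dat$phenotype, dat$genotypes,
                                   dat$grouping, 0.11)
  expect_true(max(abs(ex1$mpp - ex2$mpp)) < 0.1)
})
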