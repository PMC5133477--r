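test_that("compute_maf counts minor alleles and folds to [0, 0.5]", {
  expect_equal(compute_maf(c(0, 1, 2, 0)), 3 / 8)
  expect_equal(compute_maf(c(2, 2, 2, 2)), 0)   # monomorphic alternate
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)   # monomorphic reference
  expect_equal(compute_maf(c(0, 1, NA, 2)), 0.5)
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("compute_maf is invariant to permutation of individuals", {
  set.seed(4)
  for (i in 1:10) {
    x <- sample(c(0, 1, 2, NA), 30, replace = TRUE,
                prob = c(0.6, 0.25, 0.1, 0.05))
    if (all(is.na(x))) next
    expect_identical(compute_maf(x), compute_maf(sample(x)))
  }
})

test_that("genotype_matrix re-orients columns to count the minor allele", {
  gm <- genotype_matrix(cbind(a = c(2, 2, 1, 2), b = c(0, 1, 0, 0)))
  expect_equal(unname(gm$values[, "a"]), c(0, 0, 1, 0))
  expect_equal(unname(gm$maf), c(1 / 8, 1 / 8))
  expect_true(gm$flipped[1] && !gm$flipped[2])
  expect_error(genotype_matrix(matrix(c(0, 3), 1, 2)), "0, 1, 2")
  expect_error(genotype_matrix(matrix(0:1, 2, 2,
                                      dimnames = list(NULL, c("x", "x")))),
               "unique")
})

test_that("filter_data drops singletons, missing individuals, monomorphs", {
  vals <- cbind(v1 = c(0, 1, 1, 0), v2 = c(1, 0, 1, 2),
                v3 = c(0, 0, 0, 1))
  gm <- genotype_matrix(vals)
  ph <- phenotype_vector(c(1.2, 0.8, 1.5, 1.1))
  out <- filter_data(gm, ph, min_minor_allele_count = 1)
  expect_equal(out$genotypes$variant_ids, c("v1", "v2"))  # v3 singleton
  expect_equal(out$report$removed_variants, "v3")

  # individual with a missing genotype is dropped before the MAC recount
  vals2 <- vals; vals2[2, 1] <- NA
  out2 <- filter_data(genotype_matrix(vals2), ph)
  expect_equal(out2$genotypes$n, 3)
  expect_equal(out2$report$removed_individuals, "s2")
  # after dropping s2, v1 has MAC 1 and is now a singleton too
  expect_true("v1" %in% out2$report$removed_variants)

  # identity case: nothing missing, all MAC >= 2
  gm3 <- genotype_matrix(cbind(v1 = c(0, 1, 1, 0), v2 = c(1, 0, 1, 2)))
  out3 <- filter_data(gm3, ph)
  expect_equal(out3$genotypes$values, gm3$values)
  expect_equal(out3$phenotype$values, ph$values)

  # monomorphic variants go even with the singleton filter disabled
  gm4 <- genotype_matrix(cbind(v1 = c(0, 0, 0, 0), v2 = c(1, 0, 1, 2)),
                         orient_minor = FALSE)
  expect_equal(filter_data(gm4, ph,
                           min_minor_allele_count = 0)$genotypes$variant_ids,
               "v2")
  expect_error(filter_data(gm4, phenotype_vector(rep(NA_real_, 4))),
               "no individuals")
})

test_that("filter_data is idempotent", {
  sc <- simulation_scenario(n = 120, maf_spectrum = c(0.3, 0.05, 0.01, 0.004),
                            missing_rate = 0.02, seed = 9)
  d <- simulate_dataset(sc)
  once <- filter_data(d$genotypes, d$phenotype)
  twice <- filter_data(once$genotypes, once$phenotype)
  expect_equal(twice$genotypes$values, once$genotypes$values)
  expect_equal(twice$phenotype$values, once$phenotype$values)
  expect_equal(twice$report$n_individuals_removed, 0)
  expect_equal(twice$report$n_variants_removed, 0)
})

test_that("log_transform applies natural log and flags the result", {
  ph <- phenotype_vector(c(1, exp(1), exp(2)))
  out <- log_transform(ph)
  expect_equal(out$values, c(0, 1, 2))
  expect_true(out$log_transformed)
  expect_equal(log_transform(phenotype_vector(c(120, 80)))$values,
               c(log(120), log(80)))
  expect_error(log_transform(phenotype_vector(c(0, 1),
                                              sample_ids = c("a", "b"))),
               "'a'")
})

test_that("partition_by_maf pools rare variants and isolates common ones", {
  gm <- gm_with_mafs(c(0.343541, 0.028049, 0.002573))
  gr <- partition_by_maf(gm, 0.05)
  expect_equal(gr$n_groups, 2)
  expect_equal(gr$group_sizes[gr$group_of[1]], 1)         # common singleton
  expect_equal(gr$group_of[2], gr$group_of[3])            # shared rare group
  expect_equal(sum(gr$group_sizes), 3)

  expect_equal(partition_by_maf(gm, 0.5)$n_groups, 1)     # everything rare
  expect_equal(partition_by_maf(gm, 0.001)$n_groups, 3)   # everything common
  expect_error(partition_by_maf(gm, 0.7), "0, 0.5")
})

test_that("partition_by_maf makes one rare group per region", {
  gm <- gm_with_mafs(c(0.01, 0.3, 0.02, 0.01),
                     region = c("g1", "g1", "g2", "g2"))
  gr <- partition_by_maf(gm, 0.05)
  expect_equal(gr$n_groups, 3)
  expect_equal(gr$group_of[1] == gr$group_of[3], FALSE)
  expect_equal(gr$group_of[3], gr$group_of[4])
})

test_that("raising the MAF threshold only moves variants from common to rare", {
  set.seed(21)
  mafs <- runif(15, 0.001, 0.4)
  gm <- gm_with_mafs(mafs)
  for (i in 1:5) {
    t1 <- runif(1, 0.005, 0.2); t2 <- t1 + runif(1, 0.01, 0.25)
    common1 <- which(mafs >= t1)
    common2 <- which(mafs >= t2)
    expect_true(all(common2 %in% common1))
    # group count = common count + (any rare per region)
    expect_equal(partition_by_maf(gm, t1)$n_groups,
                 length(common1) + as.integer(length(common1) < 15))
  }
})

test_that("build_risk_design sums included dosages within groups", {
  X <- cbind(v1 = c(1, 0, 1), v2 = c(0, 2, 1))
  gm <- genotype_matrix(X, orient_minor = FALSE)
  gm$maf <- c(0.02, 0.03)
  gr <- partition_by_maf(gm, 0.05)   # one rare group
  D <- build_risk_design(gm, gr, c(1, 1))
  expect_equal(unname(D[, 1]), c(1, 2, 2))
  expect_equal(unname(build_risk_design(gm, gr, c(1, 0))[, 1]), c(1, 0, 1))
  expect_equal(ncol(build_risk_design(gm, gr, c(0, 0))), 0)
  expect_error(build_risk_design(gm, gr, c(1, 1, 1)), "dimension")
})

test_that("risk design is additive in gamma for disjoint supports", {
  dat <- tiny_assoc_data(n = 60)
  p <- dat$genotypes$p
  set.seed(5)
  for (i in 1:5) {
    g <- sample(0:2, p, replace = TRUE)
    ga <- as.integer(g == 1); gb <- as.integer(g == 2)
    Da <- build_risk_design(dat$genotypes, dat$grouping, ga)
    Db <- build_risk_design(dat$genotypes, dat$grouping, gb)
    Dab <- build_risk_design(dat$genotypes, dat$grouping, ga + gb)
    # sum columns per group on each side
    sum_by_group <- function(D) {
      if (ncol(D) == 0) return(numeric(nrow(D)))
      rowSums(D)
    }
    expect_equal(sum_by_group(Da) + sum_by_group(Db), sum_by_group(Dab))
  }
})
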