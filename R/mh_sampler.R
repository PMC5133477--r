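#' Sampler configuration
#'
#' Default protocol: 5000 burn-in iterations discarded, then every 10th state
#' kept until 5000 draws are retained, for `5000 + 5000 * 10 = 55000` total
#' iterations, with prior inclusion probability 0.1.
#'
#' @param burn_in discarded initial iterations (>= 0).
#' @param n_keep retained draws (>= 1).
#' @param thin keep one state every `thin` post-burn-in iterations (>= 1).
#' @param pip prior inclusion probability in `(0, 1)`.
#' @param seed RNG seed for the chain.
#' @param permutation_seed RNG seed for the phenotype permutation of the
#'   paired null chain (default `seed + 1`).
#' @param random_start start from a random prior draw of `gamma` instead of
#'   the all-zero model (used to check stability across starting points).
#' @return object of class `sampler_config`; `total_iterations` is always
#'   `burn_in + n_keep * thin`.
#' @export
sampler_config <- function(burn_in = 5000L, n_keep = 5000L, thin = 10L,
                           pip = 0.1, seed = 1L,
                           permutation_seed = seed + 1L,
                           random_start = FALSE) {
  stopifnot(burn_in >= 0, n_keep >= 1, thin >= 1, pip > 0, pip < 1)
  structure(list(burn_in = as.integer(burn_in), n_keep = as.integer(n_keep),
                 thin = as.integer(thin), pip = pip,
                 seed = as.integer(seed),
                 permutation_seed = as.integer(permutation_seed),
                 random_start = isTRUE(random_start),
                 total_iterations = as.integer(burn_in + n_keep * thin)),
            class = "sampler_config")
}

#' @export
print.sampler_config <- function(x, ...) {
  cat(sprintf(
    "sampler_config: burn-in %d + %d draws x thin %d = %d iterations; pip %g; seed %d\n",
    x$burn_in, x$n_keep, x$thin, x$total_iterations, x$pip, x$seed))
  invisible(x)
}

#' Single-bit-flip proposal
#'
#' Flips one uniformly chosen indicator. The kernel is symmetric, so the
#' log proposal ratio is exactly 0 and the Hastings correction vanishes.
#'
#' @param gamma binary inclusion vector (length >= 1).
#' @return list with `gamma` (the proposal), `flipped` (position), and
#'   `log_ratio` (always 0).
#' @export
propose <- function(gamma) {
  p <- length(gamma)
  stopifnot(p >= 1L)
  j <- sample.int(p, 1L)
  gamma[j] <- 1L - gamma[j]
  list(gamma = gamma, flipped = j, log_ratio = 0)
}

#' Metropolis-Hastings accept/reject step
#'
#' Accepts with probability `min(1, exp(proposed_score - current_score))`
#' (symmetric proposal assumed).
#'
#' @param current_score,proposed_score finite log posterior scores.
#' @return logical: accept the proposal?
#' @export
mh_accept <- function(current_score, proposed_score) {
  if (!is.finite(current_score) || !is.finite(proposed_score))
    stop("log scores must be finite")
  d <- proposed_score - current_score
  d >= 0 || log(stats::runif(1L)) < d
}

#' Run one Metropolis-Hastings chain over indicator space
#'
#' Starts from the all-zero model (or a prior draw when
#' `config$random_start`), performs `burn_in + n_keep * thin` single-bit-flip
#' MH iterations targeting the posterior `p(gamma | Y)` defined by the
#' plug-in likelihood and Bernoulli prior, and retains every `thin`-th
#' post-burn-in state. Fully reproducible given `config$seed`.
#'
#' @inheritParams score_state
#' @param config a [sampler_config()].
#' @param label `"observed"` or `"permuted"` (bookkeeping only).
#' @param progress_every if positive, log acceptance rate to `stderr` every
#'   this many iterations (default 0 = silent).
#' @return object of class `chain_samples`: `draws` (`n_keep x p` 0/1
#'   matrix, columns named by variant), `log_score_trace` (per retained
#'   draw), `acceptance_rate`, `n_iterations`, `config`, `label`.
#' @export
run_chain <- function(phenotype, genotypes, grouping, config,
                      label = "observed", progress_every = 0L) {
  stopifnot(inherits(config, "sampler_config"))
  scorer <- .make_scorer(phenotype, genotypes, grouping, config$pip)
  p <- genotypes$p
  total <- config$total_iterations
  set.seed(config$seed)
  gamma <- if (config$random_start)
    as.integer(stats::rbinom(p, 1L, config$pip)) else integer(p)
  js <- sample.int(p, total, replace = TRUE)
  lu <- log(stats::runif(total))
  cur <- scorer(gamma)
  draws <- matrix(0L, config$n_keep, p,
                  dimnames = list(NULL, genotypes$variant_ids))
  trace <- numeric(config$n_keep)
  acc <- 0L; kept <- 0L
  burn_in <- config$burn_in; thin <- config$thin
  for (it in seq_len(total)) {
    j <- js[it]
    gamma[j] <- 1L - gamma[j]
    prop <- scorer(gamma)
    if (prop - cur >= lu[it]) {
      cur <- prop
      acc <- acc + 1L
    } else {
      gamma[j] <- 1L - gamma[j]
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- gamma
      trace[kept] <- cur
    }
    if (progress_every > 0L && it %% progress_every == 0L)
      message(sprintf("[%s] iteration %d/%d, acceptance %.3f",
                      label, it, total, acc / it))
  }
  structure(list(draws = draws, log_score_trace = trace,
                 acceptance_rate = acc / total, n_iterations = total,
                 config = config, label = label),
            class = "chain_samples")
}

#' @export
print.chain_samples <- function(x, ...) {
  cat(sprintf(
    "chain_samples (%s): %d retained draws over %d variants; %d iterations; acceptance %.3f\n",
    x$label, nrow(x$draws), ncol(x$draws), x$n_iterations,
    x$acceptance_rate))
  invisible(x)
}

#' Randomly permute a phenotype vector
#'
#' Uniform random rearrangement of the trait values across individuals
#' (genotypes untouched), breaking any genotype-phenotype linkage while
#' preserving the trait distribution exactly. Uses the current RNG state;
#' seed with `set.seed()` or pass `seed`.
#'
#' @param phenotype a [phenotype_vector()].
#' @param seed optional seed set before permuting.
#' @return a permuted `phenotype_vector` (sample IDs keep their order; the
#'   values are rearranged).
#' @export
permute_phenotype <- function(phenotype, seed = NULL) {
  stopifnot(inherits(phenotype, "phenotype_vector"))
  if (!is.null(seed)) set.seed(seed)
  phenotype$values <- phenotype$values[sample.int(length(phenotype$values))]
  phenotype
}

#' Paired observed and permuted-phenotype chains
#'
#' Runs the observed chain on `Y` and one (or `n_permutations`) identically
#' configured null chain(s) on randomly permuted `Y*`. Chains use
#' independent seeds derived from `config$seed` (null chain `r` uses
#' `seed + 104729 * r`), so the observed chain is bit-identical whether or
#' not null chains run. The null chains' marginal posterior probabilities
#' are the per-variant empirical thresholds of the decision rule.
#'
#' @inheritParams run_chain
#' @param n_permutations number of independent permutation replicates to
#'   average the empirical MPPs over (default 1, one fixed permutation).
#' @return object of class `paired_chains`: `observed` and `null`
#'   ([run_chain()] results; `null` is the first replicate),
#'   `null_chains` (list of all replicates), `mpp`, `empirical_mpp`
#'   (averaged over replicates), `config`.
#' @export
run_paired_chains <- function(phenotype, genotypes, grouping, config,
                              n_permutations = 1L) {
  stopifnot(inherits(config, "sampler_config"), n_permutations >= 1L)
  observed <- run_chain(phenotype, genotypes, grouping, config,
                        label = "observed")
  null_chains <- vector("list", n_permutations)
  for (r in seq_len(n_permutations)) {
    ystar <- permute_phenotype(phenotype,
                               seed = config$permutation_seed + r - 1L)
    cfg_null <- config
    cfg_null$seed <- config$seed + 104729L * r
    null_chains[[r]] <- run_chain(ystar, genotypes, grouping, cfg_null,
                                  label = "permuted")
  }
  emp <- rowMeans(vapply(null_chains, compute_mpp,
                         numeric(genotypes$p)))
  names(emp) <- genotypes$variant_ids
  structure(list(observed = observed, null = null_chains[[1L]],
                 null_chains = null_chains,
                 mpp = compute_mpp(observed), empirical_mpp = emp,
                 config = config),
            class = "paired_chains")
}

#' @export
print.paired_chains <- function(x, ...) {
  cat(sprintf(
    "paired_chains: %d variants; observed acceptance %.3f; %d null chain(s)\n",
    ncol(x$observed$draws), x$observed$acceptance_rate,
    length(x$null_chains)))
  invisible(x)
}

# batch-means estimate of the spectral density of x at frequency zero,
# with ~sqrt(length) non-overlapping batches
.spectral_var0 <- function(x) {
  L <- length(x)
  nb <- max(2L, floor(sqrt(L)))
  bs <- L %/% nb
  if (bs < 1L) return(stats::var(x))
  bm <- colMeans(matrix(x[seq_len(nb * bs)], bs, nb))
  bs * stats::var(bm)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window (first `first_frac` of the trace)
#' with the mean of a late window (last `last_frac`) through a two-sample
#' z statistic whose variances are spectral-density estimates at frequency
#' zero (non-overlapping batch means, about `sqrt(window length)` batches).
#' A constant trace is reported as converged with `z = 0`.
#'
#' @param trace numeric MCMC trace (length >= 20); typically the retained
#'   log-score trace of a [run_chain()] result.
#' @param first_frac,last_frac window fractions (defaults 0.1 and 0.5,
#'   Geweke's recommendation); must sum to at most 1.
#' @param z_crit two-sided critical value for the converged flag
#'   (default 1.96).
#' @return list with `z`, `converged` (`|z| < z_crit`), window means and
#'   lengths.
#' @export
geweke_z <- function(trace, first_frac = 0.1, last_frac = 0.5,
                     z_crit = 1.96) {
  trace <- as.numeric(trace)
  L <- length(trace)
  if (L < 20L) stop("trace too short for a Geweke diagnostic (need >= 20)")
  stopifnot(first_frac > 0, last_frac > 0, first_frac + last_frac <= 1)
  na <- max(2L, floor(first_frac * L))
  nb <- max(2L, floor(last_frac * L))
  a <- trace[seq_len(na)]
  b <- trace[(L - nb + 1L):L]
  if (stats::sd(trace) == 0) {
    return(list(z = 0, converged = TRUE, mean_first = mean(a),
                mean_last = mean(b), n_first = na, n_last = nb))
  }
  vz <- .spectral_var0(a) / na + .spectral_var0(b) / nb
  dm <- mean(a) - mean(b)
  z <- if (vz > 0) dm / sqrt(vz) else if (dm == 0) 0 else sign(dm) * Inf
  list(z = z, converged = is.finite(z) && abs(z) < z_crit,
       mean_first = mean(a), mean_last = mean(b),
       n_first = na, n_last = nb)
}
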