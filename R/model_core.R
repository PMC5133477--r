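#' Log Bernoulli model-space prior
#'
#' Independent-inclusion prior `p(gamma) = prod_j pi^gamma_j (1-pi)^(1-gamma_j)`.
#' The prior inclusion probability `pi` controls the expected number of
#' included variants (`pi * p`); `pi = 0.5` is uniform over the model space.
#'
#' @param gamma binary inclusion vector.
#' @param pip prior inclusion probability, strictly inside `(0, 1)`.
#' @return log prior probability of `gamma`.
#' @export
log_prior <- function(gamma, pip) {
  if (!is.numeric(pip) || length(pip) != 1L || pip <= 0 || pip >= 1)
    stop("pip must lie strictly in (0, 1)")
  if (!all(gamma %in% c(0, 1))) stop("gamma must be binary")
  k <- sum(gamma)
  k * log(pip) + (length(gamma) - k) * log1p(-pip)
}

# sigma^2 floor guarding perfect fits: tiny fraction of trait variance
.sigma2_floor <- function(y) {
  v <- mean((y - mean(y))^2)
  1e-12 * max(v, .Machine$double.eps)
}

#' Plug-in marginal log-likelihood of a model
#'
#' Approximates `p(Y | gamma)` by the Gaussian likelihood evaluated at the
#' maximum-likelihood estimates of the model-specific parameters: an
#' ordinary least-squares fit of `Y` on an intercept plus the risk-index
#' design, with `sigma^2_hat = RSS / n` (the MLE, not the unbiased
#' estimator). The variance is floored at `1e-12 * var(Y)` so that designs
#' which interpolate the phenotype (possible with tiny carrier counts) keep
#' a finite log-likelihood. Rank-deficient designs are accepted; aliased
#' coefficients are set to zero and the RSS is unaffected.
#'
#' @param phenotype a [phenotype_vector()] or numeric vector.
#' @param design `n x m` matrix from [build_risk_design()]; `m = 0` gives
#'   the intercept-only fit.
#' @return list with `log_lik`, `beta0`, `beta` (length `m`), `sigma2`,
#'   `rss`, `df` (columns including intercept).
#' @export
plug_in_log_likelihood <- function(phenotype, design = NULL) {
  y <- if (inherits(phenotype, "phenotype_vector")) phenotype$values
       else as.numeric(phenotype)
  n <- length(y)
  if (n < 2L) stop("need at least 2 individuals")
  if (anyNA(y) || any(!is.finite(y))) stop("phenotype must be finite")
  if (is.null(design)) design <- matrix(0, n, 0)
  if (nrow(design) != n) stop("design and phenotype dimensions differ")

  if (ncol(design) == 0L) {
    beta0 <- mean(y)
    rss <- sum((y - beta0)^2)
    beta <- numeric(0)
  } else {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, design), y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    beta0 <- cf[1L]
    beta <- cf[-1L]
    rss <- sum(fit$residuals^2)
  }
  sigma2 <- max(rss / n, .sigma2_floor(y))
  log_lik <- -(n / 2) * log(2 * pi * sigma2) - n / 2
  list(log_lik = log_lik, beta0 = unname(beta0), beta = unname(beta),
       sigma2 = sigma2, rss = rss, df = ncol(design) + 1L)
}

#' Score an indicator state
#'
#' Composes [build_risk_design()], [plug_in_log_likelihood()] and
#' [log_prior()] into a fully populated indicator state: the (unnormalised)
#' log posterior score `log p(gamma) + log p(Y | gamma)` plus the fitted
#' intercept, group coefficients and residual variance.
#'
#' @inheritParams build_risk_design
#' @param phenotype a [phenotype_vector()].
#' @param pip prior inclusion probability.
#' @return object of class `indicator_state` with fields `gamma`,
#'   `log_prior`, `log_lik`, `log_score`, `beta0`, `beta`, `sigma2`.
#' @export
score_state <- function(phenotype, genotypes, grouping, gamma, pip) {
  D <- build_risk_design(genotypes, grouping, gamma)
  fit <- plug_in_log_likelihood(phenotype, D)
  lp <- log_prior(gamma, pip)
  structure(list(gamma = as.integer(gamma), log_prior = lp,
                 log_lik = fit$log_lik, log_score = lp + fit$log_lik,
                 beta0 = fit$beta0, beta = fit$beta, sigma2 = fit$sigma2,
                 active_groups = attr(D, "group_index")),
            class = "indicator_state")
}

#' @export
print.indicator_state <- function(x, ...) {
  cat(sprintf("indicator_state: %d/%d variants included, log score %.4f\n",
              sum(x$gamma), length(x$gamma), x$log_score))
  invisible(x)
}

# Fast closure scoring gamma -> log posterior score via precomputed
# centered cross-products; algebraically identical to score_state()'s
# log_score but O(m^2) per call instead of refitting on the n x m design.
# Rank-deficient normal equations fall back to the Moore-Penrose
# pseudo-inverse (minimum-norm solution; RSS unchanged).
.make_scorer <- function(phenotype, genotypes, grouping, pip) {
  y <- phenotype$values
  X <- genotypes$values
  if (anyNA(X)) stop("genotypes contain missing entries; run filter_data first")
  if (anyNA(y) || any(!is.finite(y))) stop("phenotype must be finite")
  n <- length(y)
  if (nrow(X) != n) stop("genotypes and phenotype are not aligned")
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  XtX <- crossprod(Xc)
  Xty <- drop(crossprod(Xc, yc))
  Syy <- sum(yc^2)
  if (Syy <= 0) stop("phenotype has zero variance")
  floor_s2 <- .sigma2_floor(y)
  grp <- grouping$group_of
  p <- genotypes$p
  lp1 <- log(pip); lp0 <- log1p(-pip)
  const <- -(n / 2)
  ll_empty <- const * (log(2 * pi * max(Syy / n, floor_s2)) + 1)

  function(gamma) {
    k <- sum(gamma)
    logpr <- k * lp1 + (p - k) * lp0
    if (k == 0L) return(logpr + ll_empty)
    idx <- which(gamma == 1L)
    g <- grp[idx]
    A <- rowsum(XtX[idx, idx, drop = FALSE], g)
    DtD <- t(rowsum(t(A), g))
    Dty <- drop(rowsum(Xty[idx], g))
    b <- tryCatch({
      R <- chol(DtD)
      backsolve(R, backsolve(R, Dty, transpose = TRUE))
    }, error = function(e) drop(MASS::ginv(DtD) %*% Dty))
    rss <- max(Syy - sum(b * Dty), 0)
    s2 <- max(rss / n, floor_s2)
    logpr + const * (log(2 * pi * s2) + 1)
  }
}

#' Exact posterior over all indicator states (small p)
#'
#' Enumerates every one of the `2^p` indicator vectors, scores each with the
#' plug-in likelihood and Bernoulli prior, normalises by the exact model-space
#' sum, and accumulates exact per-variant marginal posterior probabilities
#' (MPPs). Serves as the ground-truth oracle against which the
#' Metropolis-Hastings chain is validated.
#'
#' @inheritParams score_state
#' @param max_p refuse to enumerate beyond this many variants (default 20).
#' @return object of class `exact_posterior`: list with `log_scores`
#'   (length `2^p`, state index = binary encoding, variant `j` set when
#'   `bitwAnd(index - 1, 2^(j-1)) != 0`), `posterior` (normalised,
#'   sums to 1), `mpp` (length `p`, named), `pip`, `log_evidence`.
#' @export
enumerate_exact_posterior <- function(phenotype, genotypes, grouping, pip,
                                      max_p = 20L) {
  p <- genotypes$p
  if (p > max_p)
    stop("refusing exact enumeration for p = ", p, " > max_p = ", max_p)
  scorer <- .make_scorer(phenotype, genotypes, grouping, pip)
  n_states <- 2L^p
  ls <- numeric(n_states)
  gamma <- integer(p)
  for (s in 0:(n_states - 1L)) {
    gamma <- as.integer(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    ls[s + 1L] <- scorer(gamma)
  }
  m <- max(ls)
  w <- exp(ls - m)
  post <- w / sum(w)
  mpp <- vapply(seq_len(p), function(j) {
    sum(post[bitwAnd(0:(n_states - 1L), bitwShiftL(1L, j - 1L)) != 0L])
  }, numeric(1))
  names(mpp) <- genotypes$variant_ids
  structure(list(log_scores = ls, posterior = post, mpp = mpp, pip = pip,
                 log_evidence = m + log(sum(w))),
            class = "exact_posterior")
}
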