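#' Marginal posterior inclusion probabilities from chain draws
#'
#' The marginal posterior probability (MPP) of variant `j` is the posterior
#' mass of all models that include it; the Monte Carlo estimate is the
#' fraction of retained draws with `gamma_j = 1`, i.e. the column means of
#' the draw matrix.
#'
#' @param samples a [run_chain()] result, or a 0/1 draw matrix.
#' @return named numeric vector of length `p`, each entry in `[0, 1]`.
#' @export
compute_mpp <- function(samples) {
  draws <- if (inherits(samples, "chain_samples")) samples$draws else samples
  if (is.null(dim(draws)) || nrow(draws) < 1L)
    stop("no retained draws to compute MPPs from")
  colMeans(draws)
}

#' Two-stage selection of associated variants
#'
#' Stage 1 (PIP screen): a variant is selected as disease-associated when
#' its MPP strictly exceeds the prior inclusion probability. Stage 2
#' (permutation rule): a selected variant is declared a true positive when
#' its MPP additionally strictly exceeds its empirical (permuted-phenotype)
#' MPP. With `family_wise_null = TRUE` the empirical threshold is the
#' maximum empirical MPP across variants (a family-wise variant of the
#' rule; off by default, matching the per-variant thresholds the method
#' reports).
#'
#' @param mpp observed MPPs.
#' @param empirical_mpp null-chain MPPs, same length.
#' @param pip prior inclusion probability used in the analysis.
#' @param variant_ids,maf,positions optional per-variant annotation.
#' @param family_wise_null compare every variant to `max(empirical_mpp)`.
#' @return `data.frame` (class `mpp_report`) with columns `variant`, `maf`,
#'   `averaged_mpp`, `empirical_mpp`, `passes_pip`, `true_positive`, `rank`,
#'   in the input variant order; `rank` orders by descending MPP with ties
#'   broken by ascending position.
#' @export
select_variants <- function(mpp, empirical_mpp, pip, variant_ids = NULL,
                            maf = NULL, positions = NULL,
                            family_wise_null = FALSE) {
  if (length(mpp) != length(empirical_mpp))
    stop("mpp and empirical_mpp lengths differ")
  p <- length(mpp)
  if (is.null(variant_ids)) variant_ids <- names(mpp)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(p))
  if (is.null(maf)) maf <- rep(NA_real_, p)
  if (is.null(positions)) positions <- .parse_positions(variant_ids)
  threshold <- if (family_wise_null)
    rep(max(empirical_mpp), p) else empirical_mpp
  passes <- mpp > pip
  tp <- passes & (mpp > threshold)
  ord <- order(-mpp, positions)
  rank <- integer(p); rank[ord] <- seq_len(p)
  out <- data.frame(variant = variant_ids, maf = maf, averaged_mpp = mpp,
                    empirical_mpp = empirical_mpp, passes_pip = passes,
                    true_positive = tp, rank = rank,
                    stringsAsFactors = FALSE)
  attr(out, "pip") <- pip
  attr(out, "positions") <- positions
  attr(out, "family_wise_null") <- family_wise_null
  class(out) <- c("mpp_report", "data.frame")
  out
}

#' Order a report by descending MPP
#'
#' Rows are sorted by descending (averaged) MPP; ties are broken by
#' ascending variant position, so the ordering is deterministic.
#'
#' @param report an `mpp_report` from [select_variants()] or [maf_sweep()].
#' @return the same report with rows in rank order.
#' @export
rank_report <- function(report) {
  stopifnot(inherits(report, "mpp_report"))
  out <- report[order(report$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.mpp_report <- function(x, digits = 4, ...) {
  cat(sprintf("mpp_report: %d variants, pip = %g; %d pass the PIP screen, %d true positive(s)\n",
              nrow(x), attr(x, "pip"), sum(x$passes_pip),
              sum(x$true_positive)))
  print.data.frame(rank_report(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' MAF-threshold sensitivity sweep with averaged MPPs
#'
#' Re-partitions the variants at each MAF threshold, runs paired
#' observed/permuted chains per threshold (chain and permutation seeds
#' offset deterministically by threshold index), and averages each
#' variant's MPP - and its empirical MPP - arithmetically across
#' thresholds. The two-stage selection rule is applied to the averages.
#'
#' @inheritParams run_paired_chains
#' @param thresholds MAF cutoffs in `(0, 0.5]`; default
#'   `c(0.05, 0.04, 0.03, 0.02, 0.01)` (rarity definitions starting at 5%).
#' @return `mpp_report` sorted by rank, with attributes `mpp_by_threshold`
#'   and `empirical_by_threshold` (`p x length(thresholds)` matrices),
#'   `thresholds`, `geweke` (per-threshold observed-chain diagnostics),
#'   `config`, `acceptance_rates`.
#' @export
maf_sweep <- function(phenotype, genotypes, config,
                      thresholds = c(0.05, 0.04, 0.03, 0.02, 0.01),
                      n_permutations = 1L) {
  stopifnot(length(thresholds) >= 1L, all(thresholds > 0),
            all(thresholds <= 0.5))
  p <- genotypes$p
  mpp_mat <- emp_mat <- matrix(NA_real_, p, length(thresholds),
                               dimnames = list(genotypes$variant_ids,
                                               paste0("t", thresholds)))
  geweke <- vector("list", length(thresholds))
  acc <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    grouping <- partition_by_maf(genotypes, thresholds[i])
    cfg <- config
    cfg$seed <- config$seed + 7919L * (i - 1L)
    cfg$permutation_seed <- config$permutation_seed + 7919L * (i - 1L)
    pair <- run_paired_chains(phenotype, genotypes, grouping, cfg,
                              n_permutations = n_permutations)
    mpp_mat[, i] <- pair$mpp
    emp_mat[, i] <- pair$empirical_mpp
    geweke[[i]] <- geweke_z(pair$observed$log_score_trace)
    acc[i] <- pair$observed$acceptance_rate
  }
  report <- select_variants(rowMeans(mpp_mat), rowMeans(emp_mat),
                            pip = config$pip,
                            variant_ids = genotypes$variant_ids,
                            maf = genotypes$maf,
                            positions = genotypes$positions)
  report <- rank_report(report)
  attr(report, "mpp_by_threshold") <- mpp_mat
  attr(report, "empirical_by_threshold") <- emp_mat
  attr(report, "thresholds") <- thresholds
  attr(report, "geweke") <- geweke
  attr(report, "config") <- config
  attr(report, "acceptance_rates") <- acc
  report
}

#' MPP profile plot across MAF thresholds
#'
#' One line per MAF threshold of observed MPPs against variant (ordered by
#' position), a solid horizontal line at the prior inclusion probability and
#' a dotted line tracing the averaged empirical (permutation) MPPs.
#'
#' @param report a [maf_sweep()] result (needs the per-threshold attribute).
#' @param ... passed to [graphics::matplot()].
#' @export
plot_mpp_profile <- function(report, ...) {
  m <- attr(report, "mpp_by_threshold")
  if (is.null(m)) stop("report carries no per-threshold MPPs; run maf_sweep")
  ord <- order(attr(report, "positions")[match(rownames(m), report$variant)])
  m <- m[ord, , drop = FALSE]
  emp <- report$empirical_mpp[match(rownames(m), report$variant)]
  graphics::matplot(seq_len(nrow(m)), m, type = "l", lty = 1,
                    xlab = "variant", ylab = "MPP", xaxt = "n",
                    ylim = c(0, max(m, attr(report, "pip")) * 1.05), ...)
  graphics::axis(1, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  graphics::abline(h = attr(report, "pip"), col = "grey30")
  graphics::lines(seq_len(nrow(m)), emp, lty = 3, lwd = 2)
  graphics::legend("topright",
                   legend = c(paste("threshold", attr(report, "thresholds")),
                              "PIP", "empirical MPP"),
                   lty = c(rep(1, ncol(m)), 1, 3),
                   col = c(seq_len(ncol(m)), "grey30", "black"), cex = 0.7)
  invisible(report)
}
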