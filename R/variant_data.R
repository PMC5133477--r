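#' Minor allele frequency of one variant column
#'
#' Computes the frequency of the coded allele from non-missing additive
#' dosages and folds it onto `[0, 0.5]`, i.e. returns `min(f, 1 - f)` where
#' `f = sum(dosages) / (2 * n_nonmissing)`.
#'
#' @param column numeric vector of dosages in `{0, 1, 2}`; `NA` = missing.
#' @return minor allele frequency in `[0, 0.5]`.
#' @examples
#' compute_maf(c(0, 1, 2, 0))  # 3/8
#' @export
compute_maf <- function(column) {
  ok <- !is.na(column)
  if (!any(ok)) stop("variant is unusable: all genotypes missing")
  f <- sum(column[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

.parse_positions <- function(ids) {
  pos <- suppressWarnings(as.numeric(sub("^.*_", "", ids)))
  if (anyNA(pos)) pos <- seq_along(ids)
  pos
}

.parse_regions <- function(ids) {
  reg <- ifelse(grepl("_", ids), sub("_[^_]*$", "", ids), "region1")
  reg
}

#' Construct a genotype matrix object
#'
#' Wraps an `n x p` matrix of additive dosages (minor-allele counts 0/1/2,
#' `NA` = missing) together with variant identifiers, positions, region
#' labels, per-variant minor allele frequencies and a missingness mask.
#' Columns whose coded-allele frequency exceeds 0.5 are recoded as `2 - x`
#' so that dosages always count the minor allele.
#'
#' @param values `n x p` matrix; entries in `{0, 1, 2, NA}`.
#' @param variant_ids length-`p` unique labels; default column names, or
#'   `"v1"..."vp"`. IDs of the form `"<chrom>_<pos>"` are parsed for
#'   position and region.
#' @param sample_ids length-`n` labels; default row names or `"s1"..."sn"`.
#' @param region optional length-`p` region/gene labels (one rare group is
#'   formed per region); default parsed from `variant_ids`.
#' @param positions optional numeric positions used for deterministic
#'   ordering; default parsed from `variant_ids`.
#' @param orient_minor if `TRUE` (default), flip columns so the coded allele
#'   is the minor allele.
#' @return object of class `genotype_matrix` with fields `values`,
#'   `variant_ids`, `sample_ids`, `maf`, `missing_mask`, `n`, `p`,
#'   `region`, `positions`, `flipped`.
#' @export
genotype_matrix <- function(values, variant_ids = NULL, sample_ids = NULL,
                            region = NULL, positions = NULL,
                            orient_minor = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  bad <- !is.na(values) & !(values %in% c(0, 1, 2))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA (additive coding)")
  n <- nrow(values); p <- ncol(values)
  if (p < 1L) stop("genotype matrix has no variants")
  if (is.null(variant_ids)) variant_ids <- colnames(values)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(p))
  if (anyDuplicated(variant_ids)) stop("variant_ids must be unique")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (is.null(positions)) positions <- .parse_positions(variant_ids)
  if (is.null(region)) region <- .parse_regions(variant_ids)
  region <- rep_len(as.character(region), p)

  nm <- colSums(!is.na(values))
  if (any(nm == 0L)) {
    warning("variant(s) with all genotypes missing: ",
            paste(variant_ids[nm == 0L], collapse = ", "))
  }
  f <- ifelse(nm > 0L, colSums(values, na.rm = TRUE) / (2 * nm), NA_real_)
  flipped <- !is.na(f) & f > 0.5
  if (orient_minor && any(flipped)) {
    values[, flipped] <- 2 - values[, flipped]
    f[flipped] <- 1 - f[flipped]
  } else {
    flipped <- rep(FALSE, p)
  }
  maf <- pmin(f, 1 - f)
  dimnames(values) <- list(sample_ids, variant_ids)
  structure(list(values = values, variant_ids = variant_ids,
                 sample_ids = sample_ids, maf = maf,
                 missing_mask = is.na(values), n = n, p = p,
                 region = region, positions = positions, flipped = flipped),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n", x$n, x$p))
  cat(sprintf("  MAF range: %.4g - %.4g; missing entries: %d\n",
              min(x$maf, na.rm = TRUE), max(x$maf, na.rm = TRUE),
              sum(x$missing_mask)))
  invisible(x)
}

#' Construct a phenotype vector object
#'
#' @param values numeric quantitative trait, one value per individual;
#'   `NA` = missing (removed by [filter_data()]).
#' @param sample_ids optional labels (default names of `values` or
#'   `"s1"..."sn"`).
#' @param log_transformed has a log transform already been applied?
#' @return object of class `phenotype_vector` with fields `values`,
#'   `sample_ids`, `log_transformed`.
#' @export
phenotype_vector <- function(values, sample_ids = NULL,
                             log_transformed = FALSE) {
  values <- as.numeric(values)
  if (is.null(sample_ids)) sample_ids <- names(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(values))
  if (length(sample_ids) != length(values))
    stop("sample_ids and values differ in length")
  names(values) <- NULL
  structure(list(values = values, sample_ids = sample_ids,
                 log_transformed = isTRUE(log_transformed)),
            class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("phenotype_vector: n = %d%s, mean = %.4g, sd = %.4g\n",
              length(x$values), if (x$log_transformed) " (log scale)" else "",
              mean(x$values, na.rm = TRUE), stats::sd(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Natural-log transform of a phenotype
#'
#' Applied to right-skewed traits (e.g. blood pressure) before model fitting.
#' All values must be strictly positive; the error message names the first
#' offending individual.
#'
#' @param phenotype a [phenotype_vector()].
#' @return the transformed `phenotype_vector` with `log_transformed = TRUE`.
#' @export
log_transform <- function(phenotype) {
  stopifnot(inherits(phenotype, "phenotype_vector"))
  bad <- which(!is.na(phenotype$values) & phenotype$values <= 0)
  if (length(bad) > 0L)
    stop("log transform requires strictly positive values; individual '",
         phenotype$sample_ids[bad[1L]], "' has value ",
         phenotype$values[bad[1L]])
  phenotype$values <- log(phenotype$values)
  phenotype$log_transformed <- TRUE
  phenotype
}

#' Filter genotypes and phenotype for analysis
#'
#' Complete-case filtering in the order the analysis requires: individuals
#' with a missing phenotype (always) or any missing genotype (when
#' `drop_missing_individuals = TRUE`) are removed first; minor-allele counts
#' are then recomputed on the remaining individuals and variants whose MAC is
#' `<= min_minor_allele_count` (singletons, by default) or zero (monomorphic)
#' are removed. MAFs are recomputed on the filtered data. The operation is
#' idempotent.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotype a [phenotype_vector()] aligned to `genotypes` rows.
#' @param drop_missing_individuals drop individuals with any missing
#'   genotype (default `TRUE`; missing phenotypes are always dropped).
#' @param min_minor_allele_count variants with minor-allele count at or
#'   below this are removed; default 1 removes singletons. Set to 0 to keep
#'   everything polymorphic.
#' @return list with elements `genotypes`, `phenotype` and `report` (removed
#'   individual/variant IDs and counts).
#' @export
filter_data <- function(genotypes, phenotype,
                        drop_missing_individuals = TRUE,
                        min_minor_allele_count = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(phenotype, "phenotype_vector"))
  if (genotypes$n != length(phenotype$values))
    stop("genotypes and phenotype are not aligned")

  drop_ind <- is.na(phenotype$values) | !is.finite(phenotype$values)
  if (drop_missing_individuals)
    drop_ind <- drop_ind | rowSums(genotypes$missing_mask) > 0L
  keep_ind <- !drop_ind
  if (!any(keep_ind)) stop("no individuals remain after filtering")

  vals <- genotypes$values[keep_ind, , drop = FALSE]
  n2 <- nrow(vals)
  s <- colSums(vals, na.rm = TRUE)
  nm <- colSums(!is.na(vals))
  mac <- pmin(s, 2 * nm - s)
  keep_var <- nm > 0L & mac > pmax(0L, min_minor_allele_count)
  if (!any(keep_var)) stop("no variants remain after filtering")

  out <- genotype_matrix(vals[, keep_var, drop = FALSE],
                         variant_ids = genotypes$variant_ids[keep_var],
                         sample_ids = genotypes$sample_ids[keep_ind],
                         region = genotypes$region[keep_var],
                         positions = genotypes$positions[keep_var])
  ph <- phenotype_vector(phenotype$values[keep_ind],
                         sample_ids = phenotype$sample_ids[keep_ind],
                         log_transformed = phenotype$log_transformed)
  report <- list(
    removed_individuals = genotypes$sample_ids[drop_ind],
    removed_variants = genotypes$variant_ids[!keep_var],
    n_individuals_removed = sum(drop_ind),
    n_variants_removed = sum(!keep_var),
    min_minor_allele_count = min_minor_allele_count)
  list(genotypes = out, phenotype = ph, report = report)
}

#' Partition variants into rare groups and common singleton groups
#'
#' Variants with MAF strictly below `threshold` are pooled into one rare
#' group per region label; every variant at or above the threshold forms its
#' own (common) group. Groups are numbered deterministically by the position
#' of their first (lowest-position) member.
#'
#' @param genotypes a [genotype_matrix()] with MAFs computed.
#' @param threshold MAF cutoff in `(0, 0.5]` separating rare from common.
#' @return object of class `variant_grouping` with fields `threshold`,
#'   `group_of` (variant index -> group index), `group_sizes`, `n_groups`,
#'   `group_is_rare`, `group_labels`.
#' @export
partition_by_maf <- function(genotypes, threshold) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!(threshold > 0 && threshold <= 0.5))
    stop("threshold must lie in (0, 0.5]")
  if (anyNA(genotypes$maf)) stop("MAF missing for some variants; filter first")
  p <- genotypes$p
  rare <- genotypes$maf < threshold
  # provisional keys: one per region for rare variants, one per common variant
  key <- ifelse(rare, paste0("rare:", genotypes$region),
                paste0("common:", genotypes$variant_ids))
  first_pos <- tapply(genotypes$positions, key, min)
  ord <- names(sort(first_pos))
  group_of <- match(key, ord)
  sizes <- tabulate(group_of, nbins = length(ord))
  structure(list(threshold = threshold,
                 group_of = as.integer(group_of),
                 group_sizes = as.integer(sizes),
                 n_groups = length(ord),
                 group_is_rare = grepl("^rare:", ord),
                 group_labels = ord),
            class = "variant_grouping")
}

#' @export
print.variant_grouping <- function(x, ...) {
  cat(sprintf(
    "variant_grouping: %d variants -> %d groups at MAF threshold %g\n",
    length(x$group_of), x$n_groups, x$threshold))
  cat(sprintf("  rare groups: %d (sizes %s); common singletons: %d\n",
              sum(x$group_is_rare),
              paste(x$group_sizes[x$group_is_rare], collapse = ","),
              sum(!x$group_is_rare)))
  invisible(x)
}

#' Risk-index design matrix for an indicator state
#'
#' For each group with at least one included variant, produces one column
#' equal to the per-individual sum of included dosages in that group (the
#' group risk-index score; for a common singleton group simply the variant's
#' own dosage column). Groups with all indicators zero contribute no column.
#'
#' @param genotypes a [genotype_matrix()] (no missing entries; filter first).
#' @param grouping a [partition_by_maf()] result.
#' @param gamma binary inclusion vector of length `p`.
#' @return `n x m` numeric matrix, `m` = number of active groups, columns in
#'   group order, with attribute `"group_index"` giving the group each
#'   column summarises.
#' @export
build_risk_design <- function(genotypes, grouping, gamma) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(grouping, "variant_grouping"))
  p <- genotypes$p
  if (length(gamma) != p || length(grouping$group_of) != p)
    stop("gamma/grouping dimensions do not match the genotype matrix")
  if (!all(gamma %in% c(0, 1))) stop("gamma must be binary")
  idx <- which(gamma == 1)
  active <- sort(unique(grouping$group_of[idx]))
  D <- matrix(0, genotypes$n, length(active))
  for (k in seq_along(active)) {
    cols <- idx[grouping$group_of[idx] == active[k]]
    D[, k] <- rowSums(genotypes$values[, cols, drop = FALSE])
  }
  if (anyNA(D)) stop("design contains missing genotypes; run filter_data first")
  colnames(D) <- grouping$group_labels[active]
  attr(D, "group_index") <- active
  D
}
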