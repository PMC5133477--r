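#' Read genotypes from a VCF file
#'
#' Parses biallelic SNVs from a VCF (v4.x) via the GT FORMAT field:
#' `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2` (phased separators accepted),
#' `./.` or any genotype containing `.` -> missing. Multiallelic records
#' (comma in ALT) are skipped with a warning. Variant IDs follow the
#' `<CHROM>_<POS>` convention (1-based positions).
#'
#' @param path VCF file (plain or gzipped).
#' @return a [genotype_matrix()] (dosages re-oriented to count the minor
#'   allele).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  keep <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  if (!any(keep)) stop("no usable biallelic records in ", path)
  if (any(!keep))
    warning(sum(!keep), " multiallelic record(s) skipped in ", path)
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                 error = function(e) stop("VCF lacks a GT FORMAT field: ",
                                          conditionMessage(e)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  u <- unique(as.vector(gt))
  dose <- vapply(u, function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".") || length(al) == 0L) return(NA_real_)
    sum(al != "0")
  }, numeric(1))
  M <- matrix(dose[match(as.vector(gt), u)], nrow(gt), ncol(gt))
  ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")
  genotype_matrix(t(M), variant_ids = ids,
                  sample_ids = colnames(gt),
                  region = fix[, "CHROM"],
                  positions = as.numeric(fix[, "POS"]))
}

#' Write genotypes as a minimal VCF
#'
#' Emits a plain-text VCFv4.2 file with placeholder REF/ALT alleles (`A`/`C`)
#' and GT-only FORMAT, mapping dosage `0 -> 0/0`, `1 -> 0/1`, `2 -> 1/1`,
#' missing `-> ./.`. Intended for fixtures and round-tripping simulated
#' data through the VCF reader.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(genotypes$p), function(j) {
    x <- genotypes$values[, j]
    gt <- ifelse(is.na(x), "./.", gtcode[as.character(x)])
    chrom <- sub("_[^_]*$", "", genotypes$variant_ids[j])
    if (!grepl("_", genotypes$variant_ids[j])) chrom <- "1"
    paste(c(chrom, format(genotypes$positions[j], scientific = FALSE),
            genotypes$variant_ids[j], "A", "C", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##source=rvbvs",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genotypes$sample_ids),
                    collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a headered TSV matrix
#'
#' Rows are individuals, the first column (`sample_id`) their labels, the
#' remaining columns variant dosages named by variant ID.
#'
#' @param path TSV file.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d))
    stop("genotype TSV must have a 'sample_id' column")
  ids <- as.character(d$sample_id)
  m <- as.matrix(d[, setdiff(names(d), "sample_id"), drop = FALSE])
  genotype_matrix(m, sample_ids = ids)
}

#' Write genotypes as a headered TSV matrix
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  d <- data.frame(sample_id = genotypes$sample_ids,
                  genotypes$values, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV
#'
#' Expects a headered TSV with a `sample_id` column and one value column.
#' Non-numeric entries (e.g. `"NA"`) become missing and the individual is
#' dropped downstream by [filter_data()].
#'
#' @param path TSV file.
#' @param column name of the value column (default `"value"`).
#' @return a [phenotype_vector()] keyed by sample ID.
#' @export
read_phenotype_tsv <- function(path, column = "value") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d)) stop("phenotype TSV lacks 'sample_id'")
  if (!column %in% names(d))
    stop("phenotype TSV lacks column '", column, "'")
  vals <- suppressWarnings(as.numeric(d[[column]]))
  phenotype_vector(vals, sample_ids = as.character(d$sample_id))
}

#' Write a phenotype TSV
#'
#' @param phenotype a [phenotype_vector()].
#' @param path output file.
#' @param column value column name.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(phenotype, path, column = "value") {
  d <- data.frame(sample_id = phenotype$sample_ids, v = phenotype$values)
  names(d)[2L] <- column
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align genotype and phenotype samples by ID
#'
#' Joins on sample ID; individuals present in only one input are reported
#' and dropped.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotype a [phenotype_vector()].
#' @return list with aligned `genotypes`, `phenotype`, and `report`
#'   (IDs dropped from either side).
#' @export
align_samples <- function(genotypes, phenotype) {
  common <- intersect(genotypes$sample_ids, phenotype$sample_ids)
  if (length(common) == 0L) stop("no sample IDs in common")
  gi <- match(common, genotypes$sample_ids)
  pi_ <- match(common, phenotype$sample_ids)
  gm <- genotype_matrix(genotypes$values[gi, , drop = FALSE],
                        variant_ids = genotypes$variant_ids,
                        sample_ids = common,
                        region = genotypes$region,
                        positions = genotypes$positions,
                        orient_minor = FALSE)
  ph <- phenotype_vector(phenotype$values[pi_], sample_ids = common,
                         log_transformed = phenotype$log_transformed)
  report <- list(
    genotype_only = setdiff(genotypes$sample_ids, common),
    phenotype_only = setdiff(phenotype$sample_ids, common))
  if (length(report$genotype_only) + length(report$phenotype_only) > 0L)
    message(length(report$genotype_only), " genotype-only and ",
            length(report$phenotype_only),
            " phenotype-only sample(s) dropped in join")
  list(genotypes = gm, phenotype = ph, report = report)
}

#' Write a ranked MPP report as TSV
#'
#' Column layout `variant | maf | averaged_mpp | empirical_mpp |
#' passes_pip | true_positive | rank`, preceded by `#`-prefixed provenance
#' header lines (PIP, thresholds, seeds, package version) sufficient to
#' reproduce the run.
#'
#' @param report an `mpp_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "mpp_report"))
  cfg <- attr(report, "config")
  hdr <- c(
    paste0("# rvbvs ", as.character(utils::packageVersion("rvbvs")),
           " MPP report"),
    paste0("# pip: ", attr(report, "pip")),
    paste0("# maf_thresholds: ",
           paste(attr(report, "thresholds"), collapse = ",")),
    if (!is.null(cfg)) paste0(
      "# sampler: burn_in=", cfg$burn_in, " n_keep=", cfg$n_keep,
      " thin=", cfg$thin, " seed=", cfg$seed,
      " permutation_seed=", cfg$permutation_seed),
    "# empirical MPPs averaged across thresholds like observed MPPs")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(rank_report(report), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a report TSV written by [write_report_tsv()]
#'
#' @param path report file.
#' @return data.frame of the report body.
#' @export
read_report_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
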