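#' Assemble a run configuration
#'
#' Bundles input paths, filtering/transform switches, the MAF threshold
#' grid and the sampler settings for [run_pipeline()]. Can also be loaded
#' from a YAML file with [read_run_config()].
#'
#' @param genotype_file VCF (`.vcf`/`.vcf.gz`) or genotype TSV.
#' @param phenotype_file phenotype TSV.
#' @param phenotype_column value column in the phenotype TSV.
#' @param log_transform apply a natural-log transform to the trait.
#' @param maf_thresholds threshold grid for [maf_sweep()].
#' @param min_minor_allele_count singleton filter cutoff (see
#'   [filter_data()]).
#' @param n_permutations permutation replicates for the empirical null.
#' @param output_dir where [run_pipeline()] writes its artifacts.
#' @param plot also write an MPP-profile plot (PNG) to `output_dir`.
#' @param ... passed to [sampler_config()] (burn_in, n_keep, thin, pip,
#'   seed, ...).
#' @return object of class `run_config`.
#' @export
run_config <- function(genotype_file, phenotype_file,
                       phenotype_column = "value", log_transform = FALSE,
                       maf_thresholds = c(0.05, 0.04, 0.03, 0.02, 0.01),
                       min_minor_allele_count = 1L, n_permutations = 1L,
                       output_dir = ".", plot = FALSE, ...) {
  structure(list(genotype_file = genotype_file,
                 phenotype_file = phenotype_file,
                 phenotype_column = phenotype_column,
                 log_transform = isTRUE(log_transform),
                 maf_thresholds = maf_thresholds,
                 min_minor_allele_count = as.integer(min_minor_allele_count),
                 n_permutations = as.integer(n_permutations),
                 output_dir = output_dir, plot = isTRUE(plot),
                 sampler = sampler_config(...)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; sampler settings live
#' under a `sampler:` mapping.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  smp <- y$sampler %||% list()
  y$sampler <- NULL
  do.call(run_config, c(y, smp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full analysis pipeline
#'
#' Read genotypes (VCF or TSV) and phenotype, join on sample ID, filter
#' (complete cases, singleton removal), optionally log-transform the trait,
#' run the MAF-threshold sweep of paired MH chains, apply the two-stage
#' selection rule to the averaged MPPs, and write the ranked report,
#' a Geweke convergence summary and a config echo (plus an optional MPP
#' profile plot) into `config$output_dir`.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return the `mpp_report`, invisibly; artifacts on disk as a side effect.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  geno <- stage("read_genotypes", {
    if (grepl("\\.vcf(\\.gz)?$", config$genotype_file))
      read_vcf_genotypes(config$genotype_file)
    else read_genotype_tsv(config$genotype_file)
  })
  phen <- stage("read_phenotype",
                read_phenotype_tsv(config$phenotype_file,
                                   config$phenotype_column))
  al <- stage("align", align_samples(geno, phen))
  fl <- stage("filter",
              filter_data(al$genotypes, al$phenotype,
                          min_minor_allele_count =
                            config$min_minor_allele_count))
  phen <- if (config$log_transform)
    stage("log_transform", log_transform(fl$phenotype)) else fl$phenotype
  report <- stage("maf_sweep",
                  maf_sweep(phen, fl$genotypes, config$sampler,
                            thresholds = config$maf_thresholds,
                            n_permutations = config$n_permutations))

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_report_tsv(report, file.path(config$output_dir, "mpp_report.tsv"))
  gw <- attr(report, "geweke")
  gwd <- data.frame(threshold = attr(report, "thresholds"),
                    geweke_z = vapply(gw, `[[`, numeric(1), "z"),
                    converged = vapply(gw, `[[`, logical(1), "converged"),
                    acceptance_rate = attr(report, "acceptance_rates"))
  utils::write.table(gwd, file.path(config$output_dir, "geweke.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  echo <- config
  echo$sampler <- unclass(echo$sampler)
  yaml::write_yaml(unclass(echo),
                   file.path(config$output_dir, "config_echo.yaml"))
  if (config$plot) {
    grDevices::png(file.path(config$output_dir, "mpp_profile.png"),
                   width = 900, height = 500)
    plot_mpp_profile(report)
    grDevices::dev.off()
  }
  invisible(report)
}
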