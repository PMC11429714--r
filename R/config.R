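#' Run configuration
#'
#' Bundles every procedural constant of the pipeline. The defaults are the
#' values used throughout the analysis this package implements:
#' differential calling at |log2FC| >= 1.5 and adjusted p <= 0.05 (both
#' inclusive), 25 top-scoring kinases retained per phosphosite, 3 top
#' interaction scores retained per differentially expressed phosphosite, a
#' minimum overrepresentation background of 3, and gene essentiality at
#' Chronos score <= -0.5.
#'
#' @param log2fc_min minimum |log2 fold change| for a differential call
#'   (unitless, > 0)
#' @param adjp_max maximum BH-adjusted p-value for a differential call
#' @param top_kinase_percentile_count kinases retained per site after
#'   percentile ranking ("top 25 scoring kinases by percentile")
#' @param top_interactions_per_site interaction scores retained per
#'   differentially expressed phosphosite
#' @param min_background minimum number of background members a gene set needs
#'   to be tested in overrepresentation analysis
#' @param chronos_essential_max Chronos score at or below which a gene is
#'   classified essential
#' @param significance_transform transform applied to adjusted p-values before
#'   min-max normalization in regulation and activity scores:
#'   `"neglog10"` (default; weight = min-max of -log10 adj p, so the most
#'   significant site gets weight 1) or `"one_minus_p"` (min-max of 1 - p)
#' @param pathway_fraction_scale `"unit"` (default) reports the pathway-score
#'   fraction of scored phosphoproteins on 0-1; `"percent"` multiplies by 100
#' @param seed integer seed consumed by every randomized operation
#' @param paths optional named list of input file paths, carried verbatim
#' @return an object of class `run_config` (a validated list)
#' @examples
#' cfg <- run_config()
#' cfg$log2fc_min
#' @export
run_config <- function(log2fc_min = 1.5,
                       adjp_max = 0.05,
                       top_kinase_percentile_count = 25L,
                       top_interactions_per_site = 3L,
                       min_background = 3L,
                       chronos_essential_max = -0.5,
                       significance_transform = c("neglog10", "one_minus_p"),
                       pathway_fraction_scale = c("unit", "percent"),
                       seed = 1L,
                       paths = list()) {
  significance_transform <- match.arg(significance_transform)
  pathway_fraction_scale <- match.arg(pathway_fraction_scale)
  cfg <- structure(list(
    log2fc_min = as.numeric(log2fc_min),
    adjp_max = as.numeric(adjp_max),
    top_kinase_percentile_count = as.integer(top_kinase_percentile_count),
    top_interactions_per_site = as.integer(top_interactions_per_site),
    min_background = as.integer(min_background),
    chronos_essential_max = as.numeric(chronos_essential_max),
    significance_transform = significance_transform,
    pathway_fraction_scale = pathway_fraction_scale,
    seed = as.integer(seed),
    paths = paths
  ), class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a `run_config` object
#' @return `cfg`, invisibly, if valid; otherwise an error
#' @export
validate_run_config <- function(cfg) {
  if (!inherits(cfg, "run_config")) {
    pn_stop("not a run_config object", "phosnet_config_error")
  }
  if (!is.finite(cfg$log2fc_min) || cfg$log2fc_min <= 0) {
    pn_stop("log2fc_min must be > 0", "phosnet_config_error")
  }
  if (!is.finite(cfg$adjp_max) || cfg$adjp_max <= 0 || cfg$adjp_max > 1) {
    pn_stop("adjp_max must be in (0, 1]", "phosnet_config_error")
  }
  counts <- c(cfg$top_kinase_percentile_count, cfg$top_interactions_per_site,
              cfg$min_background)
  if (any(is.na(counts)) || any(counts < 1L)) {
    pn_stop("count parameters must all be >= 1", "phosnet_config_error")
  }
  if (!is.finite(cfg$chronos_essential_max)) {
    pn_stop("chronos_essential_max must be finite", "phosnet_config_error")
  }
  if (is.na(cfg$seed)) {
    pn_stop("seed must be an integer", "phosnet_config_error")
  }
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("phosnet run configuration\n")
  cat(sprintf("  differential call : |log2FC| >= %g, adj p <= %g\n",
              x$log2fc_min, x$adjp_max))
  cat(sprintf("  top kinases/site  : %d\n", x$top_kinase_percentile_count))
  cat(sprintf("  top scores/site   : %d\n", x$top_interactions_per_site))
  cat(sprintf("  ORA min background: %d\n", x$min_background))
  cat(sprintf("  essential Chronos : <= %g\n", x$chronos_essential_max))
  cat(sprintf("  seed              : %d\n", x$seed))
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' The configuration is stored as a flat key-value YAML file so that a run is
#' fully reproducible from its config and seed.
#'
#' @param path file path
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "paths")
  args <- raw[intersect(names(raw), known)]
  args$paths <- raw$paths %||% list()
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param cfg a `run_config`
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
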