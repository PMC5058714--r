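#' Run configuration for the oncomodule discovery pipeline
#'
#' Collects every tunable constant of the pipeline in one validated object.
#' Defaults reproduce the published analysis settings: discard the 30% of
#' genes with lowest variance, call differential expression at BH-adjusted
#' p < 0.05 with fallback thresholds 0.01 and 0.001 whenever more than 1000
#' genes pass, enrichment and add-back at 0.05, drivers eligible for the
#' correlation layer when mutated in at least 5 samples, knock-down extreme
#' tails at the 2.5% quantile requiring recurrence in at least 2 experiments.
#'
#' @param variance_filter_fraction Fraction of lowest-variance genes discarded
#'   before differential expression (default 0.30).
#' @param de_thresholds Strictly decreasing adjusted-p thresholds tried in
#'   order while the DE list exceeds `de_size_limit`.
#' @param de_size_limit Maximum DE-list size before the next (stricter)
#'   threshold is used.  A list of exactly this size does not advance.
#' @param enrichment_alpha Adjusted-p cutoff for a gene set to be called a
#'   significant oncomodule.
#' @param addback_raw_alpha Raw-p cutoff for adding set members back into an
#'   oncomodule after multiple-testing correction dropped them.
#' @param min_mutated_samples_for_driver_layer Minimum PAM-mutated samples
#'   for a driver to enter the driver-correlation layer.
#' @param slea_mode `"analytic"` (exact finite-population moments) or
#'   `"sampling"` (Monte-Carlo same-size random gene sets).
#' @param slea_resamples Number of random gene sets drawn in sampling mode.
#' @param slea_summary Module summary statistic, `"mean"` (default) or
#'   `"median"` (sampling mode only).
#' @param kd_extreme_quantile Tail fraction defining "extremely
#'   miss-regulated" genes in a knock-down experiment (each tail).
#' @param kd_min_experiments Number of experiments a gene must be extreme in.
#' @param mutex_permutations Permutations for the mutual-exclusivity test.
#' @param cdi_universe Contingency universe for the CRF-to-driver index:
#'   `"drivers"` (driver CRFs vs non-CRF drivers, default) or `"all_genes"`.
#' @param cdi_log_base Base of the logarithm in the CDI (default 10).
#' @param enrichment_bh_scope BH correction scope: `"collection"` (each
#'   gene-set collection is its own hypothesis family, default) or
#'   `"pooled"` (one family across collections).
#' @param strict_effects If `TRUE` (default), an unmapped mutation-effect
#'   token is a format error; otherwise it maps to `"other"` with a warning.
#' @param rng_seed Optional integer seed recorded with the run.
#'
#' @return An object of class `oda_config` (a validated named list).
#' @examples
#' cfg <- oda_config()
#' cfg$de_thresholds
#' @export
oda_config <- function(variance_filter_fraction = 0.30,
                       de_thresholds = c(0.05, 0.01, 0.001),
                       de_size_limit = 1000,
                       enrichment_alpha = 0.05,
                       addback_raw_alpha = 0.05,
                       min_mutated_samples_for_driver_layer = 5,
                       slea_mode = c("analytic", "sampling"),
                       slea_resamples = 10000,
                       slea_summary = c("mean", "median"),
                       kd_extreme_quantile = 0.025,
                       kd_min_experiments = 2,
                       mutex_permutations = 10000,
                       cdi_universe = c("drivers", "all_genes"),
                       cdi_log_base = 10,
                       enrichment_bh_scope = c("collection", "pooled"),
                       strict_effects = TRUE,
                       rng_seed = NULL) {
  slea_mode <- match.arg(slea_mode)
  slea_summary <- match.arg(slea_summary)
  cdi_universe <- match.arg(cdi_universe)
  enrichment_bh_scope <- match.arg(enrichment_bh_scope)

  stop_if(!is.numeric(variance_filter_fraction) ||
            variance_filter_fraction <= 0 || variance_filter_fraction >= 1,
          "variance_filter_fraction must lie in (0, 1)")
  stop_if(!is.numeric(de_thresholds) || length(de_thresholds) < 1 ||
            any(de_thresholds <= 0) || any(de_thresholds >= 1) ||
            any(diff(de_thresholds) >= 0),
          "de_thresholds must be strictly decreasing values in (0, 1)")
  for (nm in c("de_size_limit", "min_mutated_samples_for_driver_layer",
               "slea_resamples", "kd_min_experiments", "mutex_permutations")) {
    v <- get(nm)
    stop_if(!is.numeric(v) || length(v) != 1 || v < 1 || v != floor(v),
            sprintf("%s must be a positive integer", nm))
  }
  for (nm in c("enrichment_alpha", "addback_raw_alpha", "kd_extreme_quantile")) {
    v <- get(nm)
    stop_if(!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1,
            sprintf("%s must lie in (0, 1)", nm))
  }
  stop_if(!is.numeric(cdi_log_base) || length(cdi_log_base) != 1 ||
            cdi_log_base <= 1, "cdi_log_base must exceed 1")

  structure(list(
    variance_filter_fraction = variance_filter_fraction,
    de_thresholds = as.numeric(de_thresholds),
    de_size_limit = as.integer(de_size_limit),
    enrichment_alpha = enrichment_alpha,
    addback_raw_alpha = addback_raw_alpha,
    min_mutated_samples_for_driver_layer =
      as.integer(min_mutated_samples_for_driver_layer),
    slea_mode = slea_mode,
    slea_resamples = as.integer(slea_resamples),
    slea_summary = slea_summary,
    kd_extreme_quantile = kd_extreme_quantile,
    kd_min_experiments = as.integer(kd_min_experiments),
    mutex_permutations = as.integer(mutex_permutations),
    cdi_universe = cdi_universe,
    cdi_log_base = cdi_log_base,
    enrichment_bh_scope = enrichment_bh_scope,
    strict_effects = isTRUE(strict_effects),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "oda_config")
}

#' @export
print.oda_config <- function(x, ...) {
  cat("oncomodule discovery configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-38s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a run configuration
#'
#' Configurations are stored as YAML mirroring the [oda_config()] fields.
#'
#' @param path File path.
#' @return `read_config()` returns an `oda_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  stop_if(!file.exists(path), sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(oda_config))
  bad <- setdiff(names(vals), known)
  stop_if(length(bad) > 0,
          sprintf("unknown config fields: %s", paste(bad, collapse = ", ")))
  do.call(oda_config, vals)
}

#' @rdname read_config
#' @param config An `oda_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "oda_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# internal: stop with a plain message (no call) when cond holds
stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
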