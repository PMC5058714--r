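# CRF-to-driver index: per-sample enrichment of driver-CRF mutations,
# -log10 of a one-sided Fisher exact p-value on the 2x2 table
# [mutated driver-CRFs, unmutated driver-CRFs;
#  mutated non-CRF drivers, unmutated non-CRF drivers].

#' CRF-to-driver index of a single sample
#'
#' Measures how overrepresented driver-CRF mutations are among the sample's
#' protein-affecting mutations.  The contingency universe is the driver
#' genes: driver CRFs versus non-CRF drivers (default), or optionally all
#' genes, where non-driver genes enter the second row.
#'
#' @param sample_id Sample identifier.  A sample absent from the catalog is
#'   treated as unmutated (index 0) with a message.
#' @param catalog A `mutation_catalog`.
#' @param registry A `driver_registry` with non-empty driver-CRF and
#'   non-CRF-driver sets.
#' @param universe `"drivers"` (default) or `"all_genes"`.
#' @param log_base Logarithm base (default 10).
#' @param n_total_genes Total gene count, required for
#'   `universe = "all_genes"`.
#' @return Non-negative numeric: `-log(p)` of the one-sided (enrichment)
#'   Fisher exact test.
#' @export
sample_cdi <- function(sample_id, catalog, registry,
                       universe = c("drivers", "all_genes"),
                       log_base = 10, n_total_genes = NULL) {
  universe <- match.arg(universe)
  stopifnot(inherits(catalog, "mutation_catalog"),
            inherits(registry, "driver_registry"))
  rs <- registry_sets(registry)
  stop_if(length(rs$driver_crfs) == 0, "registry has no driver CRFs")
  stop_if(length(rs$noncrf_drivers) == 0 && universe == "drivers",
          "registry has no non-CRF drivers")

  pam <- unique(catalog$gene[catalog$sample == sample_id &
                               catalog$effect == "PAM"])
  if (!sample_id %in% catalog$sample) {
    message(sprintf("sample_cdi: sample %s absent from catalog; index 0",
                    sample_id))
  }
  a <- sum(pam %in% rs$driver_crfs)
  b <- length(rs$driver_crfs) - a
  if (universe == "drivers") {
    c_ <- sum(pam %in% rs$noncrf_drivers)
    d <- length(rs$noncrf_drivers) - c_
  } else {
    stop_if(is.null(n_total_genes),
            "n_total_genes is required for universe = 'all_genes'")
    non_crf_total <- n_total_genes - length(rs$driver_crfs)
    c_ <- sum(!pam %in% rs$driver_crfs)
    d <- non_crf_total - c_
  }
  if (a + c_ == 0) return(0)
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE),
                          alternative = "greater")$p.value
  max(0, -log(p, base = log_base))
}

#' Cohort-wide CRF-to-driver index profile
#'
#' Computes the index for every sample and summarizes the cohort
#' distribution; cohorts are comparable (and sortable) by decreasing median.
#'
#' @inheritParams sample_cdi
#' @param samples Samples to evaluate; defaults to the samples present in
#'   the catalog.  Supply the full cohort (e.g. expression column names) to
#'   include unmutated samples at index 0.
#' @return A `cdi_profile`: list with `per_sample` (data frame `sample`,
#'   `cdi`) and `summary` (median and quartiles), plus the settings used.
#' @export
cohort_cdi_profile <- function(catalog, registry, samples = NULL,
                               universe = c("drivers", "all_genes"),
                               log_base = 10, n_total_genes = NULL) {
  universe <- match.arg(universe)
  if (is.null(samples)) samples <- sort(unique(catalog$sample))
  stop_if(length(samples) < 1, "need at least one sample")
  cdi <- vapply(samples, function(s)
    suppressMessages(sample_cdi(s, catalog, registry, universe = universe,
                                log_base = log_base,
                                n_total_genes = n_total_genes)),
    numeric(1))
  qs <- stats::quantile(cdi, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    per_sample = data.frame(sample = samples, cdi = unname(cdi),
                            stringsAsFactors = FALSE),
    summary = data.frame(n = length(samples), q1 = qs[1], median = qs[2],
                         q3 = qs[3]),
    universe = universe, log_base = log_base), class = "cdi_profile")
}

#' @export
print.cdi_profile <- function(x, ...) {
  cat(sprintf(
    "CRF-to-driver index over %d samples (universe: %s, log base %g)\n",
    x$summary$n, x$universe, x$log_base))
  cat(sprintf("  median %.4g  [IQR %.4g - %.4g]\n",
              x$summary$median, x$summary$q1, x$summary$q3))
  invisible(x)
}
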