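# Orchestration: the in-memory discovery pipeline (the package's main entry
# point) and the on-disk runner with provenance report.

#' Discover oncomodules dysregulated by a driver CRF's mutations
#'
#' Runs the three discovery stages on a paired mutation/expression cohort:
#' (1) variance filter, mutation-defined grouping, per-gene rank-sum
#' differential expression with adaptive FDR thresholds; (2) hypergeometric
#' gene-set enrichment of the DE genes and oncomodule assembly with raw-p
#' add-back; (3) sample-level enrichment Z-scores for every module
#' direction, ready for evidence scoring with [score_oncomodules()].  The
#' cohort CRF-to-driver index profile is computed alongside.
#'
#' @param expression Numeric matrix, genes x samples (normalized,
#'   median-centered).
#' @param mutations A `mutation_catalog`.
#' @param registry A `driver_registry`.
#' @param gene_sets List of `gene_set_collection`s.
#' @param focal_crf Focal driver-CRF gene id.
#' @param config An [oda_config()].
#' @return An object of class `oda_fit`: list with `focal_crf`, `config`,
#'   `groups`, `detable`, `de_genes`, `threshold_used`, `universe`,
#'   `enrichment`, `modules`, `slea`, `cdi`.
#' @examples
#' bundle <- simulate_cohort(n_samples = 60, n_genes = 300, seed = 4)
#' fit <- discover_oncomodules(bundle$expression, bundle$mutations,
#'                             bundle$registry, bundle$gene_sets, "CRF1")
#' print(fit)
#' @export
discover_oncomodules <- function(expression, mutations, registry, gene_sets,
                                 focal_crf, config = oda_config()) {
  stopifnot(is.matrix(expression), inherits(mutations, "mutation_catalog"),
            inherits(registry, "driver_registry"))
  filtered <- variance_filter(expression, config$variance_filter_fraction)
  groups <- define_groups(mutations, registry, focal_crf,
                          samples = colnames(expression))
  detable <- differential_expression(filtered, groups)
  sel <- select_de_genes(detable, config$de_thresholds, config$de_size_limit)
  detable <- sel$detable
  universe <- rownames(filtered)
  enrichment <- enrich_collections(sel$de_genes, gene_sets, universe,
                                   alpha = config$enrichment_alpha,
                                   bh_scope = config$enrichment_bh_scope)
  modules <- assemble_oncomodules(enrichment, detable, gene_sets,
                                  addback_raw_alpha = config$addback_raw_alpha)
  global_up <- detable$gene[detable$de_flag & detable$direction == "up"]
  global_down <- detable$gene[detable$de_flag & detable$direction == "down"]
  slea <- slea_matrix(filtered, modules, global_up, global_down,
                      mode = config$slea_mode,
                      summary = config$slea_summary,
                      n_resamples = config$slea_resamples,
                      seed = config$rng_seed)
  cdi <- cohort_cdi_profile(mutations, registry,
                            samples = colnames(expression),
                            universe = config$cdi_universe,
                            log_base = config$cdi_log_base,
                            n_total_genes = nrow(expression))
  structure(list(focal_crf = focal_crf, config = config, groups = groups,
                 detable = detable, de_genes = sel$de_genes,
                 threshold_used = sel$threshold_used, universe = universe,
                 enrichment = enrichment, modules = modules, slea = slea,
                 cdi = cdi), class = "oda_fit")
}

#' @export
print.oda_fit <- function(x, ...) {
  cat(sprintf("oncomodule discovery for focal CRF %s\n", x$focal_crf))
  cat(sprintf("  groups: %d mutated / %d control (%d excluded)\n",
              length(x$groups$mutated), length(x$groups$control),
              length(x$groups$excluded)))
  cat(sprintf("  universe after variance filter: %d genes\n",
              length(x$universe)))
  cat(sprintf("  DE genes: %d (%d up, %d down) at adjusted p < %g\n",
              length(x$de_genes),
              sum(x$detable$de_flag & x$detable$direction == "up"),
              sum(x$detable$de_flag & x$detable$direction == "down"),
              x$threshold_used))
  cat(sprintf("  significant oncomodules: %d of %d sets tested\n",
              sum(x$enrichment$significant), nrow(x$enrichment)))
  for (m in x$modules)
    cat(sprintf("    %s (%d up / %d down)\n", m$name,
                length(m$up_set), length(m$down_set)))
  invisible(x)
}

#' @export
summary.oda_fit <- function(object, ...) {
  print(object)
  if (sum(object$enrichment$significant) > 0) {
    cat("\nenrichment of significant sets:\n")
    print(object$enrichment[object$enrichment$significant,
                            c("set", "query", "term", "overlap", "adj_p")],
          row.names = FALSE)
  }
  cat(sprintf("\ncohort CRF-to-driver index: median %.3g\n",
              object$cdi$summary$median))
  invisible(object)
}

#' Run the full pipeline against on-disk inputs and write all artifacts
#'
#' Stages communicate only through files in the package's documented
#' formats, so every stage is independently re-runnable.  Outputs:
#' `groups.tsv`, `detable.tsv`, `enrichment.tsv`, `modules.gmt`,
#' `slea.tsv`, `cdi.tsv`, optionally `scorecard.tsv` and `mutex.tsv`, plus
#' `report.json` (config snapshot, seed, file digests, timings, warnings).
#'
#' @param input_dir Directory holding `expression.tsv`, `mutations.tsv`,
#'   `registry.tsv` and one or more `.gmt` files (e.g. written by
#'   [write_cohort_bundle()]), or `NULL` when `bundle` is given.
#' @param outdir Output directory (created if needed).
#' @param focal_crf Focal CRF gene id.
#' @param config An [oda_config()].
#' @param bundle Optional in-memory `cohort_bundle` (used instead of
#'   `input_dir`).
#' @param priors,panel,tissue,kd Optional evidence-scoring inputs (see
#'   [score_oncomodules()]); the scorecard stage runs when at least `priors`
#'   is given or modules exist.
#' @param mutex_genes Optional gene set for the mutual-exclusivity stage.
#' @param seed Seed recorded in the report and used for seeded stages.
#' @return A `run_report` (invisibly the `oda_fit` as attribute `fit`).
#' @export
run_pipeline <- function(input_dir = NULL, outdir, focal_crf,
                         config = oda_config(), bundle = NULL,
                         priors = NULL, panel = NULL, tissue = NULL,
                         kd = NULL, mutex_genes = NULL, seed = 1L) {
  stop_if(is.null(input_dir) && is.null(bundle),
          "supply input_dir or a cohort bundle")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c(); warns <- character()
  wh <- function(w) { warns <<- c(warns, conditionMessage(w))
                      invokeRestart("muffleWarning") }
  config$rng_seed <- as.integer(seed)

  if (is.null(bundle)) {
    expression <- read_expression(file.path(input_dir, "expression.tsv"))
    mutations <- read_mutations(file.path(input_dir, "mutations.tsv"),
                                strict = config$strict_effects)
    registry <- read_registry(file.path(input_dir, "registry.tsv"))
    gmt <- list.files(input_dir, "\\.gmt$", full.names = TRUE)
    stop_if(length(gmt) == 0, "no .gmt gene-set files in input_dir")
    gene_sets <- lapply(gmt, read_gene_sets)
  } else {
    expression <- bundle$expression; mutations <- bundle$mutations
    registry <- bundle$registry; gene_sets <- bundle$gene_sets
  }
  timings["load"] <- proc.time()[["elapsed"]] - t0; t0 <- proc.time()[["elapsed"]]

  fit <- withCallingHandlers(
    discover_oncomodules(expression, mutations, registry, gene_sets,
                         focal_crf, config),
    warning = wh)
  timings["discover"] <- proc.time()[["elapsed"]] - t0; t0 <- proc.time()[["elapsed"]]

  files <- character()
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files[[name]] <<- unname(tools::md5sum(path))
  }
  emit("groups.tsv", function(p) write_table(data.frame(
    sample = c(fit$groups$mutated, fit$groups$control, fit$groups$excluded),
    group = rep(c("mutated", "control", "excluded"),
                c(length(fit$groups$mutated), length(fit$groups$control),
                  length(fit$groups$excluded)))), p))
  emit("detable.tsv", function(p) write_table(fit$detable, p))
  emit("enrichment.tsv", function(p) write_table(fit$enrichment, p))
  emit("modules.gmt", function(p) write_oncomodules(fit$modules, p))
  emit("slea.tsv", function(p) write_expression(unclass(fit$slea), p,
                                                rowname_header = "row"))
  emit("cdi.tsv", function(p) write_table(fit$cdi$per_sample, p))

  if (length(fit$modules) > 0) {
    scorecard <- withCallingHandlers(
      score_oncomodules(fit$modules, fit$slea, mutations, registry,
                        focal_crf, priors = priors, panel = panel,
                        tissue = tissue, kd = kd, config = config),
      warning = wh)
    emit("scorecard.tsv", function(p) write_table(scorecard, p))
  } else scorecard <- NULL
  timings["score"] <- proc.time()[["elapsed"]] - t0; t0 <- proc.time()[["elapsed"]]

  if (!is.null(mutex_genes)) {
    am <- alteration_matrix(mutations, mutex_genes,
                            samples = colnames(expression))
    mx <- withCallingHandlers(
      mutex_test(am, n_permutations = config$mutex_permutations,
                 seed = seed), warning = wh)
    layout <- sort_exclusive_layout(am)
    emit("mutex.tsv", function(p) write_table(data.frame(
      coverage = mx$coverage, n_permutations = mx$n_permutations,
      n_as_extreme = mx$n_as_extreme, p = mx$p), p))
    emit("mutex_layout.tsv", function(p)
      write_expression(layout$matrix, p, rowname_header = "gene"))
  }
  timings["mutex"] <- proc.time()[["elapsed"]] - t0

  report <- structure(list(seed = as.integer(seed),
                           config = unclass(config),
                           files = as.list(files),
                           timings = as.list(round(timings, 3)),
                           warnings = warns), class = "run_report")
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  attr(report, "fit") <- fit
  attr(report, "scorecard") <- scorecard
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  cat(sprintf("  seed: %d\n", x$seed))
  cat("  artifacts (md5):\n")
  for (nm in names(x$files)) cat(sprintf("    %-18s %s\n", nm, x$files[[nm]]))
  if (length(x$warnings) > 0) {
    cat("  warnings:\n")
    for (w in unique(x$warnings)) cat(sprintf("    - %s\n", w))
  }
  invisible(x)
}
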