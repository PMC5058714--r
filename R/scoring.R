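# Stage 3: the evidence layers and the scorecard aggregation.
#
# Seven layers per oncomodule: driver_correlation and (when panels are
# supplied) cellline and kd_overlap are computed; cm02 (Connectivity Map
# drug list) and the three prior-literature layers are external inputs
# supplied as a priors table.  Aggregation: one point per favorable layer,
# NA layers leave the denominator, and a module whose Z-scores correlate
# better with another driver's mutations than with the focal CRF's is
# disqualified outright (overall NA).

LAYER_IDS <- c("driver_correlation", "cm02", "prior_crf", "prior_tumor",
               "prior_cancer", "cellline", "kd_overlap")

#' Construct a layer result
#'
#' @param layer One of `driver_correlation`, `cm02`, `prior_crf`,
#'   `prior_tumor`, `prior_cancer`, `cellline`, `kd_overlap`.
#' @param verdict `positive`, `negative`, `NA`, or (only for
#'   `driver_correlation`) `disqualify`.
#' @param detail Layer-specific payload (ranking table, drug list,
#'   p-values).
#' @return A `layer_result`.
#' @export
layer_result <- function(layer, verdict, detail = NULL) {
  layer <- match.arg(layer, LAYER_IDS)
  verdict <- match.arg(verdict, c("positive", "negative", "NA", "disqualify"))
  stop_if(verdict == "disqualify" && layer != "driver_correlation",
          "disqualify is only legal for the driver_correlation layer")
  structure(list(layer = layer, verdict = verdict, detail = detail),
            class = "layer_result")
}

#' Driver-correlation evidence layer
#'
#' For every driver mutated (PAM) in at least `min_mutated` cohort samples,
#' compares the module's SLEA Z-scores between that driver's mutated and
#' unmutated samples (two-sided Wilcoxon) and ranks the p-values.  The layer
#' is positive when the focal CRF attains the smallest p-value; otherwise
#' the module is explained at least as well by another driver and is
#' disqualified (Occam's razor).
#'
#' @param slea_row Named numeric vector: the module's Z-score per sample.
#' @param catalog A `mutation_catalog` covering the cohort.
#' @param registry A `driver_registry`.
#' @param focal_crf Focal CRF gene id (must itself reach `min_mutated`).
#' @param min_mutated Minimum mutated samples for a driver to enter
#'   (default 5).
#' @return A `layer_result` with verdict `positive` or `disqualify` and a
#'   detail data frame (`driver`, `n_mutated`, `p`, `rank`).
#' @export
driver_correlation_layer <- function(slea_row, catalog, registry, focal_crf,
                                     min_mutated = 5) {
  samples <- names(slea_row)
  stop_if(is.null(samples), "slea_row must be named by sample")
  z <- slea_row[!is.na(slea_row)]
  samples <- names(z)
  pam <- catalog[catalog$effect == "PAM" & catalog$sample %in% samples, ,
                 drop = FALSE]
  drivers <- registry$gene[registry$is_driver]
  n_mut <- vapply(drivers, function(g)
    length(unique(pam$sample[pam$gene == g])), integer(1))
  eligible <- drivers[n_mut >= min_mutated]
  stop_if(!focal_crf %in% eligible,
          sprintf("focal CRF '%s' is mutated in fewer than %d samples",
                  focal_crf, min_mutated))
  p <- vapply(eligible, function(g) {
    mut <- samples %in% pam$sample[pam$gene == g]
    wilcox_p(z[mut], z[!mut])[2]
  }, numeric(1))
  detail <- data.frame(driver = eligible,
                       n_mutated = n_mut[match(eligible, drivers)],
                       p = unname(p), stringsAsFactors = FALSE)
  detail <- detail[order(detail$p, detail$driver), , drop = FALSE]
  detail$rank <- seq_len(nrow(detail))
  rownames(detail) <- NULL
  focal_first <- detail$p[detail$driver == focal_crf] <= min(detail$p)
  layer_result("driver_correlation",
               if (focal_first) "positive" else "disqualify", detail)
}

#' Cell-line miss-regulation evidence layer
#'
#' Computes SLEA Z-scores of the module's up and down subsets across the
#' panel's cell lines of the matched tissue, compares mutated versus
#' wild-type lines per subset (two-sided Wilcoxon, BH across the tests in
#' the call), and scores positive when any subset is significant *and* its
#' shift direction matches the tumor-derived direction (up subset higher in
#' mutated lines, down subset lower).  Returns `NA` when the focal CRF's
#' mutation status is not assayed in the panel or either group has fewer
#' than 2 lines.
#'
#' @param panel A `cellline_panel`.
#' @param oncomodule An `oncomodule`.
#' @param focal_crf Focal CRF gene id.
#' @param tissue Tissue label to restrict the panel to (must exist).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param adj_p Optional externally BH-adjusted p-values (named `up`/`down`)
#'   when correction is performed across several modules by the caller.
#' @return A `layer_result` with a detail data frame per subset.
#' @export
cellline_layer <- function(panel, oncomodule, focal_crf, tissue,
                           alpha = 0.05, adj_p = NULL) {
  stopifnot(inherits(panel, "cellline_panel"), inherits(oncomodule, "oncomodule"))
  stop_if(!tissue %in% panel$tissue,
          sprintf("unknown tissue label '%s'", tissue))
  lines_ <- names(panel$tissue)[panel$tissue == tissue]
  if (!focal_crf %in% panel$assayed_genes)
    return(layer_result("cellline", "NA",
                        detail = "focal CRF mutation status not assayed"))
  pam <- panel$mutations[panel$mutations$effect == "PAM", , drop = FALSE]
  mut <- lines_[lines_ %in% pam$sample[pam$gene == focal_crf]]
  wt <- setdiff(lines_, mut)
  if (length(mut) < 2 || length(wt) < 2)
    return(layer_result("cellline", "NA",
                        detail = "fewer than 2 lines in a group"))
  tests <- compute_cellline_tests(panel, list(oncomodule), mut, wt)
  if (nrow(tests) == 0)
    return(layer_result("cellline", "NA", detail = "module empty in panel"))
  tests$adj_p <- if (is.null(adj_p)) stats::p.adjust(tests$p, "BH")
                 else unname(adj_p[tests$subset])
  pos <- any(tests$adj_p < alpha & tests$concordant)
  layer_result("cellline", if (pos) "positive" else "negative", tests)
}

# analytic SLEA Z of one gene set across every column of expr
analytic_slea_row <- function(expr, genes) {
  N <- nrow(expr)
  k <- length(genes)
  mu <- colMeans(expr)
  sig <- sqrt(colMeans(expr^2) - mu^2)
  mvals <- colMeans(expr[genes, , drop = FALSE])
  if (k == N) return(stats::setNames(rep(0, ncol(expr)), colnames(expr)))
  se <- sig * sqrt((N - k) / (N - 1)) / sqrt(k)
  z <- (mvals - mu) / se
  z[sig == 0] <- NA_real_
  z
}

# Wilcoxon mutated-vs-wildtype SLEA comparison per module direction subset;
# shared by cellline_layer and the run-level BH across modules.
compute_cellline_tests <- function(panel, modules, mut, wt) {
  expr <- panel$expression[, c(mut, wt), drop = FALSE]
  rows <- list()
  for (m in modules) {
    for (dir in c("up", "down")) {
      genes <- intersect(m[[paste0(dir, "_set")]], rownames(expr))
      if (length(genes) == 0) next
      z <- analytic_slea_row(expr, genes)
      zm <- z[mut]; zw <- z[wt]
      if (anyNA(zm) || anyNA(zw)) next
      p <- wilcox_p(zm, zw)[2]
      shift <- stats::median(zm) - stats::median(zw)
      conc <- if (dir == "up") shift > 0 else shift < 0
      rows[[paste(m$name, dir, sep = "_")]] <-
        data.frame(module = m$name, subset = dir, n_mut = length(mut),
                   n_wt = length(wt), p = p, shift = shift,
                   concordant = conc, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(module = character(), subset = character(),
                      n_mut = integer(), n_wt = integer(), p = numeric(),
                      shift = numeric(), concordant = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recurrently extreme genes across knock-down experiments of one target
#'
#' Per experiment, the `floor(q * N)` genes with the largest and the
#' `floor(q * N)` with the smallest z-values are extreme; the consensus set
#' holds genes extreme in at least `min_experiments` experiments.
#'
#' @param experiments List of named numeric z-vectors over a shared
#'   universe.
#' @param q Tail quantile (default 0.025, each tail).
#' @param min_experiments Required recurrence (default 2).
#' @return Character vector of genes, or `NULL` when fewer than
#'   `min_experiments` experiments are available (the caller's `NA` signal).
#' @export
extreme_gene_set <- function(experiments, q = 0.025, min_experiments = 2) {
  if (length(experiments) < min_experiments) return(NULL)
  uni <- names(experiments[[1]])
  for (e in experiments)
    stop_if(!identical(sort(names(e)), sort(uni)),
            "experiments must share the assayed universe")
  n_tail <- floor(q * length(uni))
  stop_if(n_tail < 1, "tail quantile too small for the universe size")
  counts <- stats::setNames(integer(length(uni)), uni)
  for (e in experiments) {
    ord <- order(e, xtfrm(names(e)))      # deterministic under ties
    extreme <- c(names(e)[ord[seq_len(n_tail)]],
                 names(e)[ord[length(e) - seq_len(n_tail) + 1]])
    counts[extreme] <- counts[extreme] + 1L
  }
  sort(names(counts)[counts >= min_experiments])
}

#' Knock-down signature overlap evidence layer
#'
#' Run only for modules unequivocally controlled by one gene (a defined
#' controller).  Builds the consensus extreme gene sets of the focal CRF and
#' of the controller from their knock-down experiments, and tests their
#' overlap over the assayed universe with a one-sided Fisher exact test
#' (enrichment).
#'
#' @param kd A `kd_catalog`.
#' @param focal_crf Focal CRF gene id.
#' @param controller_gene Controller of the module, or `NA` (layer `NA`).
#' @param q,min_experiments Passed to [extreme_gene_set()].
#' @param alpha Significance cutoff on the (possibly externally adjusted)
#'   p-value (default 0.05).
#' @param adj_p Optional BH-adjusted p-value when the caller corrects across
#'   modules.
#' @return A `layer_result`; detail holds the 2x2 table and p-value.
#' @export
knockdown_overlap_layer <- function(kd, focal_crf, controller_gene,
                                    q = 0.025, min_experiments = 2,
                                    alpha = 0.05, adj_p = NULL) {
  stopifnot(inherits(kd, "kd_catalog"))
  if (is.null(controller_gene) || is.na(controller_gene))
    return(layer_result("kd_overlap", "NA",
                        detail = "module has no controller gene"))
  for (g in c(focal_crf, controller_gene)) {
    if (!g %in% names(kd$experiments) || length(kd$experiments[[g]]) < 1)
      return(layer_result("kd_overlap", "NA",
                          detail = sprintf("no knock-down experiments for %s", g)))
  }
  set_a <- extreme_gene_set(kd$experiments[[focal_crf]], q, min_experiments)
  set_b <- extreme_gene_set(kd$experiments[[controller_gene]], q,
                            min_experiments)
  if (is.null(set_a) || is.null(set_b))
    return(layer_result("kd_overlap", "NA",
                        detail = sprintf("fewer than %d experiments",
                                         min_experiments)))
  N <- length(kd$universe)
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  c_ <- length(set_b) - a
  d <- N - a - b - c_
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE),
                          alternative = "greater")$p.value
  p_use <- if (is.null(adj_p)) p else adj_p
  detail <- data.frame(in_both = a, focal_only = b, controller_only = c_,
                       neither = d, p = p, adj_p = p_use)
  layer_result("kd_overlap", if (p_use < alpha) "positive" else "negative",
               detail)
}

#' Aggregate seven evidence layers into a scorecard
#'
#' Numerator: count of positive verdicts (the driver-correlation layer is
#' positive when no other driver correlates better; the cm02 layer when its
#' drug list is non-empty).  Denominator: `7 - (number of NA layers)`.  A
#' disqualified driver-correlation layer voids the module: overall `NA`.
#'
#' @param layers List of exactly seven `layer_result`s, one per layer id.
#' @return A `scorecard`: list with `layers`, `numerator`, `denominator`,
#'   `overall` (e.g. `"5/6"`, or `NA`).
#' @export
aggregate_scorecard <- function(layers) {
  ids <- vapply(layers, `[[`, "", "layer")
  stop_if(length(layers) != 7 || anyDuplicated(ids) > 0 ||
            !setequal(ids, LAYER_IDS),
          "need exactly one layer_result per layer id")
  layers <- layers[match(LAYER_IDS, ids)]
  verdicts <- vapply(layers, `[[`, "", "verdict")
  names(verdicts) <- LAYER_IDS
  if (verdicts["driver_correlation"] == "disqualify") {
    return(structure(list(layers = layers, verdicts = verdicts,
                          numerator = NA_integer_, denominator = NA_integer_,
                          overall = NA_character_), class = "scorecard"))
  }
  numerator <- sum(verdicts == "positive")
  denominator <- 7L - sum(verdicts == "NA")
  overall <- if (denominator == 0) {
    warning("all layers NA; overall score undefined")
    NA_character_
  } else sprintf("%d/%d", numerator, denominator)
  structure(list(layers = layers, verdicts = verdicts,
                 numerator = as.integer(numerator),
                 denominator = as.integer(denominator), overall = overall),
            class = "scorecard")
}

#' @export
print.scorecard <- function(x, ...) {
  cat("evidence scorecard:\n")
  for (nm in names(x$verdicts))
    cat(sprintf("  %-20s %s\n", nm, x$verdicts[nm]))
  cat(sprintf("  overall: %s\n",
              if (is.na(x$overall)) "NA (disqualified or empty)" else x$overall))
  invisible(x)
}

#' Layer results from an external priors table
#'
#' The Connectivity Map drug layer and the three literature layers are
#' external judgements, supplied per module as a drug list string (empty,
#' `""`, `"No"` or `NA` means none) and three booleans (`NA` allowed).
#'
#' @param priors_row One row of a priors data frame with columns
#'   `cm02_drugs`, `prior_crf`, `prior_tumor`, `prior_cancer`.
#' @return List of four `layer_result`s.
#' @export
prior_layers <- function(priors_row) {
  drugs <- priors_row$cm02_drugs
  has_drugs <- !is.na(drugs) && nzchar(trimws(drugs)) &&
    tolower(trimws(drugs)) != "no"
  out <- list(layer_result("cm02", if (has_drugs) "positive" else "negative",
                           detail = drugs))
  for (nm in c("prior_crf", "prior_tumor", "prior_cancer")) {
    v <- priors_row[[nm]]
    verdict <- if (is.na(v)) "NA" else if (isTRUE(as.logical(v))) "positive"
               else "negative"
    out <- c(out, list(layer_result(nm, verdict)))
  }
  out
}

#' Score a set of oncomodules
#'
#' Builds the seven layers per module — the driver-correlation layer from
#' the cohort SLEA matrix, the cell-line and knock-down layers from optional
#' panels (BH-corrected across all modules scored in the call), and the four
#' external layers from the priors table — and aggregates each scorecard.
#'
#' @param modules List of `oncomodule`s.
#' @param slea A `slea_matrix` over the cohort.
#' @param catalog,registry Cohort mutation catalog and driver registry.
#' @param focal_crf Focal CRF gene id.
#' @param priors Data frame with columns `module`, `cm02_drugs`,
#'   `prior_crf`, `prior_tumor`, `prior_cancer` (missing modules get `NA`
#'   drug list and priors).
#' @param panel Optional `cellline_panel`.
#' @param tissue Tissue label for the panel.
#' @param kd Optional `kd_catalog`.
#' @param config An [oda_config()].
#' @return A data frame (one row per module) with the seven verdicts and
#'   the overall score, plus attribute `scorecards` (the full objects).
#' @export
score_oncomodules <- function(modules, slea, catalog, registry, focal_crf,
                              priors = NULL, panel = NULL, tissue = NULL,
                              kd = NULL, config = oda_config()) {
  stop_if(length(modules) == 0, "no oncomodules to score")
  mnames <- vapply(modules, `[[`, "", "name")

  # computed layers needing run-level BH: cell line and knock-down
  cl_tests <- NULL
  if (!is.null(panel) && !is.null(tissue)) {
    cl_all <- lapply(modules, function(m)
      cellline_layer(panel, m, focal_crf, tissue,
                     alpha = config$enrichment_alpha))
    ps <- unlist(lapply(cl_all, function(l)
      if (is.data.frame(l$detail)) l$detail$p else NULL))
    adj <- stats::p.adjust(ps, "BH")
    i <- 0
    cl_tests <- lapply(cl_all, function(l) {
      if (!is.data.frame(l$detail)) return(l)
      k <- nrow(l$detail)
      l$detail$adj_p <- adj[i + seq_len(k)]
      i <<- i + k
      pos <- any(l$detail$adj_p < config$enrichment_alpha &
                   l$detail$concordant)
      layer_result("cellline", if (pos) "positive" else "negative", l$detail)
    })
  }
  kd_layers <- NULL
  if (!is.null(kd)) {
    kd_raw <- lapply(modules, function(m)
      knockdown_overlap_layer(kd, focal_crf, m$controller,
                              q = config$kd_extreme_quantile,
                              min_experiments = config$kd_min_experiments,
                              alpha = config$enrichment_alpha))
    ps <- vapply(kd_raw, function(l)
      if (is.data.frame(l$detail)) l$detail$p else NA_real_, numeric(1))
    adj <- stats::p.adjust(ps[!is.na(ps)], "BH")
    j <- 0
    kd_layers <- lapply(kd_raw, function(l) {
      if (!is.data.frame(l$detail)) return(l)
      j <<- j + 1
      l$detail$adj_p <- adj[j]
      layer_result("kd_overlap",
                   if (adj[j] < config$enrichment_alpha) "positive"
                   else "negative", l$detail)
    })
  }

  cards <- vector("list", length(modules))
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    up_row <- paste0(m$name, "_up"); down_row <- paste0(m$name, "_down")
    rows_avail <- intersect(c(up_row, down_row), rownames(slea))
    zr <- NULL
    best <- Inf
    dc <- NULL
    for (r in rows_avail) {
      z <- slea[r, ]
      if (all(is.na(z))) next
      cand <- driver_correlation_layer(
        z, catalog, registry, focal_crf,
        min_mutated = config$min_mutated_samples_for_driver_layer)
      pf <- cand$detail$p[cand$detail$driver == focal_crf]
      if (pf < best) { best <- pf; dc <- cand }
    }
    stop_if(is.null(dc),
            sprintf("no usable SLEA row for module '%s'", m$name))

    pr <- if (!is.null(priors) && m$name %in% priors$module)
      priors[priors$module == m$name, , drop = FALSE]
    else data.frame(module = m$name, cm02_drugs = NA_character_,
                    prior_crf = NA, prior_tumor = NA, prior_cancer = NA)
    ext <- prior_layers(pr[1, ])

    cl <- if (!is.null(cl_tests)) cl_tests[[i]]
          else layer_result("cellline", "NA", detail = "no panel supplied")
    kdl <- if (!is.null(kd_layers)) kd_layers[[i]]
           else layer_result("kd_overlap", "NA", detail = "no catalog supplied")
    cards[[i]] <- aggregate_scorecard(c(list(dc), ext, list(cl, kdl)))
  }
  names(cards) <- mnames
  out <- data.frame(module = mnames, stringsAsFactors = FALSE)
  for (nm in LAYER_IDS)
    out[[nm]] <- vapply(cards, function(cc) cc$verdicts[[nm]], "")
  out$overall <- vapply(cards, function(cc)
    if (is.na(cc$overall)) NA_character_ else cc$overall, "")
  rownames(out) <- NULL
  attr(out, "scorecards") <- cards
  out
}
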