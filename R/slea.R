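# Sample-Level Enrichment Analysis: per-sample Z-scores measuring the
# collective over/under-expression of a gene module relative to same-size
# random gene sets drawn from the same sample.
#
# Analytic mode uses the exact moments of the mean of k values drawn without
# replacement from the sample's N values: mean mu (the sample's grand mean)
# and standard error sigma * sqrt((N - k) / (N - 1)) / sqrt(k) with sigma the
# population standard deviation, i.e. the finite-population correction.
# Sampling mode estimates the same null by Monte-Carlo.

#' SLEA Z-score of one module in one sample
#'
#' @param sample_values Named numeric vector: the sample's expression over
#'   the tested universe (length >= 2).
#' @param module_genes Genes of the module subset (must lie in the universe,
#'   at least one).
#' @param mode `"analytic"` (default) or `"sampling"`.
#' @param summary Module summary statistic: `"mean"` (default) or
#'   `"median"`; the median is only available in sampling mode.
#' @param n_resamples Random same-size gene sets in sampling mode.
#' @param seed Optional seed for sampling mode.
#' @return The Z-score; `NA` (degenerate) when the sample's values have zero
#'   variance.  A module spanning the whole universe has Z = 0 by
#'   construction.
#' @export
slea_zscore <- function(sample_values, module_genes,
                        mode = c("analytic", "sampling"),
                        summary = c("mean", "median"),
                        n_resamples = 10000, seed = NULL) {
  mode <- match.arg(mode)
  summary <- match.arg(summary)
  N <- length(sample_values)
  k <- length(module_genes)
  stop_if(N < 2, "universe must hold at least 2 genes")
  stop_if(k < 1, "module must hold at least one gene")
  stop_if(k > N, "module larger than the universe")
  miss <- setdiff(module_genes, names(sample_values))
  stop_if(length(miss) > 0,
          sprintf("module genes outside the universe: %s...",
                  paste(utils::head(miss, 3), collapse = ", ")))
  stop_if(summary == "median" && mode == "analytic",
          "median summary requires sampling mode")

  sigma2 <- mean((sample_values - mean(sample_values))^2)
  if (sigma2 == 0) return(NA_real_)
  stat <- if (summary == "mean") mean else stats::median
  m <- stat(sample_values[module_genes])
  if (mode == "analytic") {
    if (k == N) return(0)
    mu <- mean(sample_values)
    se <- sqrt(sigma2) * sqrt((N - k) / (N - 1)) / sqrt(k)
    return((m - mu) / se)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  null_means <- vapply(seq_len(n_resamples), function(i)
    stat(sample_values[sample.int(N, k)]), numeric(1))
  s <- stats::sd(null_means)
  if (s == 0) return(NA_real_)
  (m - mean(null_means)) / s
}

#' SLEA Z-score matrix for a set of oncomodules
#'
#' One row per oncomodule direction subset plus two rows for the global up-
#' and down-regulated DE sets (so 3 modules give 8 rows).  Row order is
#' deterministic: modules by name, up before down, globals last.  Empty
#' subsets produce a degenerate all-`NA` row, flagged in the `degenerate`
#' attribute.
#'
#' @param expr Numeric matrix over the tested universe (genes x samples).
#' @param modules List of `oncomodule`s.
#' @param global_up,global_down Character vectors: all up-/down-regulated DE
#'   genes.
#' @param mode,summary,n_resamples,seed Passed to [slea_zscore()].
#' @return A `slea_matrix`: numeric matrix (rows x samples) with attributes
#'   `degenerate` (logical per row) and `mode`.
#' @export
slea_matrix <- function(expr, modules, global_up, global_down,
                        mode = c("analytic", "sampling"),
                        summary = c("mean", "median"),
                        n_resamples = 10000, seed = NULL) {
  mode <- match.arg(mode)
  summary <- match.arg(summary)
  ord <- order(vapply(modules, `[[`, "", "name"))
  modules <- modules[ord]
  rows <- list()
  for (m in modules) {
    rows[[paste0(m$name, "_up")]] <- m$up_set
    rows[[paste0(m$name, "_down")]] <- m$down_set
  }
  rows[["DE_up"]] <- global_up
  rows[["DE_down"]] <- global_down

  out <- matrix(NA_real_, length(rows), ncol(expr),
                dimnames = list(names(rows), colnames(expr)))
  degenerate <- stats::setNames(rep(FALSE, length(rows)), names(rows))
  if (mode == "analytic" && summary == "mean") {
    # vectorized over samples: column moments once, module means per row
    N <- nrow(expr)
    mu <- colMeans(expr)
    sig <- sqrt(colMeans(expr^2) - mu^2)
    for (nm in names(rows)) {
      genes <- intersect(rows[[nm]], rownames(expr))
      k <- length(genes)
      if (k == 0) { degenerate[nm] <- TRUE; next }
      mvals <- colMeans(expr[genes, , drop = FALSE])
      if (k == N) { out[nm, ] <- 0; next }
      se <- sig * sqrt((N - k) / (N - 1)) / sqrt(k)
      z <- (mvals - mu) / se
      z[sig == 0] <- NA_real_
      out[nm, ] <- z
      if (anyNA(z)) degenerate[nm] <- TRUE
    }
  } else {
    seeds <- if (is.null(seed)) rep(list(NULL), ncol(expr))
             else as.list(split_seed(seed, ncol(expr)))
    for (nm in names(rows)) {
      genes <- intersect(rows[[nm]], rownames(expr))
      if (length(genes) == 0) { degenerate[nm] <- TRUE; next }
      out[nm, ] <- vapply(seq_len(ncol(expr)), function(j)
        slea_zscore(stats::setNames(expr[, j], rownames(expr)), genes,
                    mode = mode, summary = summary,
                    n_resamples = n_resamples, seed = seeds[[j]]),
        numeric(1))
      if (anyNA(out[nm, ])) degenerate[nm] <- TRUE
    }
  }
  if (any(degenerate))
    warning(sprintf("slea_matrix: degenerate row(s): %s",
                    paste(names(rows)[degenerate], collapse = ", ")))
  structure(out, degenerate = degenerate, mode = mode, class = "slea_matrix")
}

#' @export
print.slea_matrix <- function(x, ...) {
  cat(sprintf("SLEA Z-score matrix: %d rows x %d samples (%s mode)\n",
              nrow(x), ncol(x), attr(x, "mode")))
  print(unclass(x)[, seq_len(min(5, ncol(x))), drop = FALSE])
  if (ncol(x) > 5) cat(sprintf("... %d more samples\n", ncol(x) - 5))
  invisible(x)
}
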