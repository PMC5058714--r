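# Stage 1 of the discovery pipeline: variance filter, mutation-defined
# sample grouping, per-gene Wilcoxon rank-sum tests with BH correction, and
# the adaptive DE-threshold rule.

#' Discard the lowest-variance genes
#'
#' Variance is computed across *all* samples regardless of mutation status
#' (population form, divisor n).  The `ceil((1 - fraction) * n_genes)`
#' highest-variance genes are retained; ties at the cut are broken in favor
#' of the lexicographically larger gene id, so the retained set is
#' deterministic.
#'
#' @param expr Numeric matrix, genes as rows.
#' @param fraction Fraction of genes to discard, in (0, 1); default 0.30.
#' @return The filtered matrix (original row order preserved).
#' @export
variance_filter <- function(expr, fraction = 0.30) {
  stop_if(!is.numeric(fraction) || fraction <= 0 || fraction >= 1,
          "fraction must lie in (0, 1)")
  stop_if(ncol(expr) < 2, "variance undefined with fewer than 2 samples")
  n <- nrow(expr)
  keep_n <- ceiling((1 - fraction) * n)
  mu <- rowMeans(expr)
  v <- rowMeans((expr - mu)^2)          # population variance
  ord <- order(-v, -xtfrm(rownames(expr)))
  keep <- sort(ord[seq_len(keep_n)])
  expr[keep, , drop = FALSE]
}

#' Partition cohort samples by focal-CRF mutation status
#'
#' The mutated group holds samples with at least one protein-affecting
#' mutation (PAM) of the focal CRF (focal membership dominates any other
#' mutation the sample carries); the control group holds samples with zero
#' PAMs in *every* driver CRF; all remaining samples (mutated in some other
#' driver CRF but not the focal one) are excluded from the comparison.
#'
#' @param catalog A `mutation_catalog`.
#' @param registry A `driver_registry`; `focal_crf` must be one of its
#'   driver CRFs.
#' @param focal_crf Focal CRF gene id.
#' @param samples Full cohort sample ids (e.g. expression column names);
#'   defaults to the samples present in the catalog.
#' @return A `group_assignment`: list with `focal_crf`, `mutated`,
#'   `control`, `excluded` (character vectors, pairwise disjoint).
#' @export
define_groups <- function(catalog, registry, focal_crf, samples = NULL) {
  stopifnot(inherits(catalog, "mutation_catalog"),
            inherits(registry, "driver_registry"))
  rs <- registry_sets(registry)
  stop_if(!focal_crf %in% rs$driver_crfs,
          sprintf("focal CRF '%s' is not a driver CRF in the registry",
                  focal_crf))
  if (is.null(samples)) samples <- sort(unique(catalog$sample))
  pam <- catalog[catalog$effect == "PAM", , drop = FALSE]
  focal_mut <- samples %in% pam$sample[pam$gene == focal_crf]
  any_crf <- samples %in% pam$sample[pam$gene %in% rs$driver_crfs]
  mutated <- samples[focal_mut]
  control <- samples[!any_crf]
  excluded <- samples[any_crf & !focal_mut]
  stop_if(length(mutated) == 0,
          sprintf("mutated group is empty for focal CRF '%s'", focal_crf))
  stop_if(length(control) == 0,
          "control group (samples with no driver-CRF mutations) is empty")
  structure(list(focal_crf = focal_crf, mutated = mutated, control = control,
                 excluded = excluded), class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("groups for %s: %d mutated, %d control, %d excluded\n",
              x$focal_crf, length(x$mutated), length(x$control),
              length(x$excluded)))
  invisible(x)
}

# Two-sided Wilcoxon rank-sum p-value for x (group 1) vs y (group 2).
# Exact enumeration (pwilcox) when both groups <= exact_max and there are no
# ties; otherwise normal approximation with tie and continuity correction.
# Returns c(W, p) with W the Mann-Whitney statistic of group 1.
wilcox_p <- function(x, y, exact_max = 10) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  all_v <- c(x, y)
  r <- rank(all_v)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(all_v) > 0
  if (!has_ties && n1 <= exact_max && n2 <= exact_max) {
    p <- min(1, 2 * min(stats::pwilcox(W, n1, n2),
                        stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)))
    return(c(W, p))
  }
  sig2 <- n1 * n2 / 12 * (N + 1)
  if (has_ties) {
    nt <- tabulate(match(all_v, unique(all_v)))
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
  }
  if (sig2 <= 0) return(c(W, 1))      # constant across both groups
  z <- W - n1 * n2 / 2
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sig2)
  c(W, min(1, 2 * stats::pnorm(-abs(z))))
}

#' Per-gene differential expression between mutated and control samples
#'
#' Two-sided Wilcoxon rank-sum test per gene (exact enumeration when both
#' groups have at most `exact_max` samples and no ties; tie- and
#' continuity-corrected normal approximation otherwise), followed by
#' Benjamini-Hochberg correction across all tested genes.  Direction is the
#' sign of (median mutated - median control); a zero median difference falls
#' back to the mean difference; a gene constant in both groups gets p = 1
#' and direction `"none"`.
#'
#' @param expr Numeric matrix, genes as rows (already variance-filtered).
#' @param groups A `group_assignment`; both groups need at least 2 samples
#'   present in `expr`.
#' @param exact_max Largest group size for the exact path (default 10).
#' @return A `de_table`: data frame with columns `gene`, `statistic`
#'   (Mann-Whitney W of the mutated group), `raw_p`, `adj_p`, `direction`
#'   (`up`/`down`/`none`), `de_flag` (filled by [select_de_genes()]).
#' @export
differential_expression <- function(expr, groups, exact_max = 10) {
  stopifnot(inherits(groups, "group_assignment"))
  g1 <- intersect(groups$mutated, colnames(expr))
  g2 <- intersect(groups$control, colnames(expr))
  stop_if(length(g1) < 2, "mutated group has fewer than 2 samples in expr")
  stop_if(length(g2) < 2, "control group has fewer than 2 samples in expr")
  n1 <- length(g1)
  sub <- expr[, c(g1, g2), drop = FALSE]
  res <- t(apply(sub, 1, function(v)
    wilcox_p(v[seq_len(n1)], v[-seq_len(n1)], exact_max = exact_max)))
  raw_p <- res[, 2]
  med1 <- apply(sub[, seq_len(n1), drop = FALSE], 1, stats::median)
  med2 <- apply(sub[, -seq_len(n1), drop = FALSE], 1, stats::median)
  d <- med1 - med2
  zero <- d == 0
  if (any(zero)) {
    m1 <- rowMeans(sub[zero, seq_len(n1), drop = FALSE])
    m2 <- rowMeans(sub[zero, -seq_len(n1), drop = FALSE])
    d[zero] <- m1 - m2
  }
  direction <- ifelse(d > 0, "up", ifelse(d < 0, "down", "none"))
  const_both <- apply(sub, 1, function(v) all(v == v[1]))
  if (any(const_both)) {
    raw_p[const_both] <- 1
    direction[const_both] <- "none"
    message(sprintf(
      "differential_expression: %d gene(s) constant in both groups (p = 1)",
      sum(const_both)))
  }
  out <- data.frame(gene = rownames(sub), statistic = res[, 1],
                    raw_p = raw_p, adj_p = stats::p.adjust(raw_p, "BH"),
                    direction = direction, de_flag = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- groups
  class(out) <- c("de_table", "data.frame")
  out
}

#' Select differentially expressed genes with the adaptive threshold rule
#'
#' Starts at the first (loosest) adjusted-p threshold; while more than
#' `size_limit` genes pass and a stricter threshold remains, advances to it.
#' Exactly `size_limit` passing genes does not advance.
#'
#' @param detable A `de_table` from [differential_expression()].
#' @param thresholds Strictly decreasing adjusted-p thresholds
#'   (default `c(0.05, 0.01, 0.001)`).
#' @param size_limit DE-list size that triggers the next threshold
#'   (default 1000).
#' @return List with `de_genes` (character), `threshold_used`, and
#'   `detable` (input with `de_flag` set and attribute `threshold_used`).
#' @export
select_de_genes <- function(detable, thresholds = c(0.05, 0.01, 0.001),
                            size_limit = 1000) {
  stop_if(any(diff(thresholds) >= 0), "thresholds must be strictly decreasing")
  i <- 1
  repeat {
    n_de <- sum(detable$adj_p < thresholds[i])
    if (n_de <= size_limit || i == length(thresholds)) break
    i <- i + 1
  }
  thr <- thresholds[i]
  detable$de_flag <- detable$adj_p < thr
  attr(detable, "threshold_used") <- thr
  list(de_genes = detable$gene[detable$de_flag], threshold_used = thr,
       detable = detable)
}
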