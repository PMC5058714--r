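# Mutual-exclusivity permutation test over a binary alteration matrix, with
# the oncoprint-style staircase layout.

#' Binary alteration matrix from a mutation catalog
#'
#' @param catalog A `mutation_catalog`.
#' @param genes Genes of interest (rows).
#' @param samples Cohort sample ids (columns); defaults to catalog samples.
#' @param pam_only Count only protein-affecting mutations (default `TRUE`).
#' @return Binary matrix, genes x samples.
#' @export
alteration_matrix <- function(catalog, genes, samples = NULL,
                              pam_only = TRUE) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  if (is.null(samples)) samples <- sort(unique(catalog$sample))
  rec <- if (pam_only) catalog[catalog$effect == "PAM", , drop = FALSE]
         else catalog
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  rec <- rec[rec$gene %in% genes & rec$sample %in% samples, , drop = FALSE]
  m[cbind(rec$gene, rec$sample)] <- 1L
  m
}

#' Permutation test for mutual exclusivity of alterations
#'
#' The statistic is the coverage: the number of samples carrying at least
#' one alteration of the gene set.  Each permutation independently shuffles
#' every gene's alterations across the samples, preserving its alteration
#' count exactly, and the one-sided empirical p-value with add-one smoothing
#' is `(1 + #{coverage >= observed}) / (1 + n_permutations)`.  Small
#' p-values mean the alterations spread over more samples than chance
#' placement allows, i.e. mutual exclusivity.
#'
#' @param mat Binary matrix (genes x samples), entries 0/1.
#' @param n_permutations Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A `mutex_result`: list with `coverage` (observed),
#'   `n_permutations`, `n_as_extreme` (permutations with coverage at least
#'   the observed), `p`.
#' @export
mutex_test <- function(mat, n_permutations = 10000, seed = NULL) {
  stop_if(!is.matrix(mat) || nrow(mat) < 1 || ncol(mat) < 1,
          "need a matrix with at least one gene and one sample")
  stop_if(!all(mat %in% c(0, 1)), "alteration matrix must be binary")
  stop_if(n_permutations < 1, "n_permutations must be at least 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  counts <- rowSums(mat)
  n_s <- ncol(mat)
  observed <- sum(colSums(mat) > 0)
  if (observed == 0) {
    warning("all-zero alteration matrix; coverage 0, p = 1")
    return(structure(list(coverage = 0L, n_permutations = n_permutations,
                          n_as_extreme = n_permutations, p = 1),
                     class = "mutex_result"))
  }
  hits <- 0L
  covered <- logical(n_s)
  for (b in seq_len(n_permutations)) {
    covered[] <- FALSE
    for (g in seq_along(counts)) {
      if (counts[g] > 0) covered[sample.int(n_s, counts[g])] <- TRUE
    }
    if (sum(covered) >= observed) hits <- hits + 1L
  }
  structure(list(coverage = as.integer(observed),
                 n_permutations = as.integer(n_permutations),
                 n_as_extreme = hits,
                 p = (1 + hits) / (1 + n_permutations)),
            class = "mutex_result")
}

#' @export
print.mutex_result <- function(x, ...) {
  cat(sprintf(
    "mutual exclusivity: coverage %d; empirical p = %.4g (%d/%d permutations)\n",
    x$coverage, x$p, x$n_as_extreme, x$n_permutations))
  invisible(x)
}

#' Oncoprint-style staircase layout of an alteration matrix
#'
#' Genes are sorted by descending alteration count (ties by gene id);
#' samples are sorted by the gene-ordered alteration tuple (altered-first),
#' ties by sample id, producing the canonical staircase.  The output is
#' invariant to the input's row and column order.
#'
#' @param mat Binary matrix (genes x samples).
#' @return List with `genes`, `samples` (the orders) and `matrix` (the
#'   re-arranged input).
#' @export
sort_exclusive_layout <- function(mat) {
  stop_if(!is.matrix(mat) || nrow(mat) < 1 || ncol(mat) < 1,
          "need a non-empty matrix")
  gene_ord <- order(-rowSums(mat), rownames(mat))
  m2 <- mat[gene_ord, , drop = FALSE]
  keys <- c(lapply(seq_len(nrow(m2)), function(i) -m2[i, ]),
            list(colnames(m2)))
  samp_ord <- do.call(order, keys)
  m3 <- m2[, samp_ord, drop = FALSE]
  list(genes = rownames(m3), samples = colnames(m3), matrix = m3)
}
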