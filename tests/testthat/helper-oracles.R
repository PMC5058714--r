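# Independent brute-force oracles used to check the package's statistics.
# These deliberately avoid the code paths they verify (phyper, p.adjust,
# fisher.test, the package's wilcox_p).

# upper-tail hypergeometric by direct summation over choose()
oracle_hyper_tail <- function(k, q, t, N) {
  if (k <= 0) return(1)
  i <- k:min(q, t)
  # log-space summation so large tables neither overflow nor underflow
  sum(exp(lchoose(t, i) + lchoose(N - t, q - i) - lchoose(N, q)))
}

# one-sided (enrichment) Fisher p for table [a, b; c, d] by tail summation
oracle_fisher_greater <- function(a, b, c, d) {
  oracle_hyper_tail(a, a + c, a + b, a + b + c + d)
}

# BH step-up by the textbook recipe: sort descending, cummin of p * n / rank
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- cummin(p[o] * n / (n:1))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# exact two-sided rank-sum p by enumeration of all C(n1+n2, n1) group
# assignments of the pooled values (handles ties by construction)
oracle_wilcox_exact <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x); N <- length(all_v)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(N, n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# exact null distribution of the mutex coverage statistic for tiny matrices:
# enumerate every placement of each gene's alterations
oracle_mutex_coverage <- function(counts, n_samples) {
  placements <- lapply(counts, function(k)
    if (k == 0) list(integer()) else
      asplit(utils::combn(n_samples, k), 2))
  grid <- expand.grid(lapply(placements, seq_along))
  cov <- apply(grid, 1, function(idx) {
    hit <- unique(unlist(mapply(function(pl, i) pl[[i]], placements, idx,
                                SIMPLIFY = FALSE)))
    length(hit)
  })
  table(factor(cov, levels = 0:n_samples)) / length(cov)
}

# small deterministic fixtures -------------------------------------------

toy_registry <- function() {
  driver_registry(
    gene = c("CRFA", "CRFB", "DRV1", "DRV2", "GENE1"),
    is_driver = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    is_crf = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    mode = c("LoF", "LoF", "unknown", "Act", "unknown"))
}

toy_catalog <- function() {
  mutation_catalog(
    sample = c("S1", "S1", "S2", "S3", "S3", "S4"),
    gene   = c("CRFA", "DRV1", "DRV2", "CRFB", "CRFA", "GENE1"),
    effect = c("missense", "nonsense", "missense", "frameshift", "splice",
               "silent"))
}

# run differential_expression on a bare matrix: first n1 columns mutated,
# the rest control
diffexp_fixture <- function(mat, n1, exact_max = 10) {
  if (is.null(colnames(mat))) colnames(mat) <- paste0("S", seq_len(ncol(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("G", seq_len(nrow(mat)))
  g <- structure(list(focal_crf = "X",
                      mutated = colnames(mat)[seq_len(n1)],
                      control = colnames(mat)[-seq_len(n1)],
                      excluded = character()), class = "group_assignment")
  differential_expression(mat, g, exact_max = exact_max)
}
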