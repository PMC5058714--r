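test_that("variance filter keeps the right count with deterministic ties", {
  set.seed(1)
  mat <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("G", 0:9), NULL))
  colnames(mat) <- c("S1", "S2")
  out <- variance_filter(mat, 0.30)
  expect_identical(nrow(out), 7L)        # ceil(0.7 * 10)

  # a constant gene is always among the discarded when fraction > 0
  mat["G3", ] <- 5
  expect_false("G3" %in% rownames(variance_filter(mat, 0.30)))

  # identical variances: retained set decided purely by the tie rule
  tie <- matrix(rep(c(0, 1), 10), 10, 2, byrow = TRUE,
                dimnames = list(paste0("G", 0:9), c("S1", "S2")))
  kept <- rownames(variance_filter(tie, 0.30))
  # sort oracle: variance desc, then lexicographically larger id first
  v <- apply(tie, 1, function(x) mean((x - mean(x))^2))
  oracle <- sort(rownames(tie)[order(-v, -xtfrm(rownames(tie)))][1:7])
  expect_identical(sort(kept), oracle)
  expect_identical(sort(kept), sort(paste0("G", 3:9)))

  expect_error(variance_filter(mat[, 1, drop = FALSE], 0.3), "2 samples")
})

test_that("group definition follows the PAM precedence rules", {
  reg <- toy_registry()
  # 5 focal-mutated, 6 CRF-clean, 3 other-CRF-mutated samples; one sample
  # carries both the focal and another CRF's PAM; one has only a silent
  # focal mutation
  samples <- paste0("P", 1:14)
  cat_ <- mutation_catalog(
    sample = c("P1", "P2", "P3", "P4", "P5", "P5",
               "P12", "P13", "P14", "P6"),
    gene   = c("CRFA", "CRFA", "CRFA", "CRFA", "CRFA", "CRFB",
               "CRFB", "CRFB", "CRFB", "CRFA"),
    effect = c(rep("missense", 9), "silent"))
  g <- define_groups(cat_, reg, "CRFA", samples = samples)
  expect_setequal(g$mutated, paste0("P", 1:5))         # P5: focal dominates
  expect_setequal(g$control, paste0("P", 6:11))        # P6 silent -> control
  expect_setequal(g$excluded, paste0("P", 12:14))
  expect_length(intersect(g$mutated, g$control), 0)

  expect_error(define_groups(cat_, reg, "DRV1", samples = samples),
               "not a driver CRF")
  only_focal <- mutation_catalog(samples, rep("CRFA", 14),
                                 rep("missense", 14))
  expect_error(define_groups(only_focal, reg, "CRFA", samples = samples),
               "control group")
})

test_that("rank-sum p-values match exact enumeration", {
  # {1,2,3} vs {4,5,6}: all 20 assignments, two-sided p = 0.1
  de <- diffexp_fixture(rbind(A = c(1, 2, 3, 4, 5, 6)), 3)
  expect_equal(de$raw_p, 0.1, tolerance = 1e-12)
  expect_identical(de$direction, "down")

  # identical values in both groups -> p = 1, no direction
  de <- suppressMessages(diffexp_fixture(rbind(A = rep(2, 8)), 4))
  expect_identical(de$raw_p, 1)
  expect_identical(de$direction, "none")

  # random small cases vs the enumeration oracle (exact path, incl. ties)
  set.seed(99)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:8, n1 + n2, replace = TRUE)  # ties likely
    de <- diffexp_fixture(rbind(A = x), n1)
    p_or <- oracle_wilcox_exact(x[seq_len(n1)], x[-seq_len(n1)])
    if (anyDuplicated(x)) {
      # tied data go through the corrected normal approximation, whose
      # error can reach ~0.15 at these tiny heavily-tied sizes
      expect_lt(abs(de$raw_p - p_or), 0.2)
    } else {
      expect_equal(de$raw_p, p_or, tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment matches the step-up oracle", {
  de <- diffexp_fixture(matrix(c(1, 2, 3, 10, 11, 12,
                                 5, 1, 6, 2, 7, 3,
                                 1, 3, 2, 9, 10, 11,
                                 4, 4, 4, 4, 4, 5),
                               4, 6, byrow = TRUE,
                               dimnames = list(paste0("G", 1:4), NULL)), 3)
  expect_equal(de$adj_p, oracle_bh(de$raw_p), tolerance = 1e-12)
  expect_true(all(de$adj_p >= de$raw_p))

  # hand example: raw (0.01, 0.02, 0.03, 0.04) -> all adjusted to 0.04
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # property: 200 random p-vectors
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("adaptive DE threshold rule advances only above the size limit", {
  mk <- function(counts) {
    # build an adj_p vector realizing the given counts below .05/.01/.001
    n <- 2000
    adj <- rep(0.5, n)
    adj[seq_len(counts[1])] <- 0.049
    adj[seq_len(counts[2])] <- 0.009
    adj[seq_len(counts[3])] <- 0.0009
    structure(data.frame(gene = paste0("G", 1:n), statistic = 0,
                         raw_p = adj, adj_p = adj, direction = "up",
                         de_flag = FALSE, stringsAsFactors = FALSE),
              class = c("de_table", "data.frame"))
  }
  r <- select_de_genes(mk(c(1200, 640, 100)))
  expect_identical(r$threshold_used, 0.01)
  expect_length(r$de_genes, 640)
  r <- select_de_genes(mk(c(1500, 1200, 300)))
  expect_identical(r$threshold_used, 0.001)
  expect_length(r$de_genes, 300)
  r <- select_de_genes(mk(c(154, 80, 10)))
  expect_identical(r$threshold_used, 0.05)
  expect_length(r$de_genes, 154)
  # exactly the size limit does not advance
  r <- select_de_genes(mk(c(1000, 400, 10)))
  expect_identical(r$threshold_used, 0.05)
  expect_length(r$de_genes, 1000)
})
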