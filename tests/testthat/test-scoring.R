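# helper: build the seven layers from compact verdict codes
# P = positive, N = negative, A = NA, D = disqualify (driver layer only)
layers_from_codes <- function(codes) {
  stopifnot(length(codes) == 7)
  map <- c(P = "positive", N = "negative", A = "NA", D = "disqualify")
  mapply(function(id, code) layer_result(id, map[[code]]),
         c("driver_correlation", "cm02", "prior_crf", "prior_tumor",
           "prior_cancer", "cellline", "kd_overlap"),
         codes, SIMPLIFY = FALSE)
}

test_that("scorecard aggregation reproduces the published scorecard rows", {
  # the ten top-scoring modules across five CRFs and four tumor types, as
  # (driver-correlation has-better-driver?, drug list, three priors,
  # cell-line, knock-down overlap) -> overall
  rows <- list(
    # HNSC / MLL2
    mTOR      = list(c("P", "P", "N", "P", "P", "A", "P"), "5/6"),
    E2F1      = list(c("P", "N", "P", "P", "P", "A", "P"), "5/6"),
    # HNSC / NSD1
    MEK       = list(c("P", "P", "P", "P", "P", "A", "A"), "5/5"),
    AKT1      = list(c("P", "P", "N", "P", "P", "A", "P"), "5/6"),
    # LUAD / SMARCA4
    SOX9      = list(c("P", "P", "N", "P", "P", "P", "A"), "5/6"),
    HSF       = list(c("P", "P", "P", "P", "P", "N", "A"), "5/6"),
    # KIRC / PBRM1
    p53       = list(c("P", "P", "P", "P", "P", "N", "P"), "6/7"),
    ERBB2     = list(c("P", "P", "N", "N", "P", "N", "P"), "4/7"),
    # KIRC / BAP1
    BER       = list(c("P", "P", "P", "P", "P", "N", "A"), "5/6"),
    CD28      = list(c("P", "P", "N", "P", "P", "N", "A"), "4/6"),
    # UCEC / ARID1A: another driver (TP53) correlates better -> disqualified
    p53_ucec  = list(c("D", "N", "P", "P", "P", "N", "A"), NA_character_),
    junction  = list(c("D", "P", "N", "P", "P", "N", "A"), NA_character_))
  for (nm in names(rows)) {
    sc <- aggregate_scorecard(layers_from_codes(rows[[nm]][[1]]))
    expect_identical(sc$overall, rows[[nm]][[2]], label = nm)
  }
})

test_that("aggregation degenerate cases and verdict algebra", {
  sc <- aggregate_scorecard(layers_from_codes(c("P", "A", "A", "A", "A",
                                                "A", "A")))
  expect_identical(sc$overall, "1/1")
  expect_warning(
    sc0 <- aggregate_scorecard(layers_from_codes(rep("A", 7))),
    "all layers NA")
  expect_true(is.na(sc0$overall))

  # flipping one negative to positive raises the numerator by exactly 1
  base <- c("P", "N", "N", "P", "A", "N", "P")
  sc1 <- aggregate_scorecard(layers_from_codes(base))
  for (i in which(base == "N")) {
    flip <- base; flip[i] <- "P"
    sc2 <- aggregate_scorecard(layers_from_codes(flip))
    expect_identical(sc2$numerator, sc1$numerator + 1L)
    expect_identical(sc2$denominator, sc1$denominator)
  }

  expect_error(aggregate_scorecard(layers_from_codes(base)[1:6]),
               "exactly one")
  expect_error(layer_result("cm02", "disqualify"), "only legal")
})

test_that("prior layers translate the external evidence table", {
  pr <- data.frame(module = "M", cm02_drugs = "rapamycin, vorinostat",
                   prior_crf = FALSE, prior_tumor = TRUE, prior_cancer = NA)
  ls_ <- prior_layers(pr)
  v <- vapply(ls_, `[[`, "", "verdict")
  expect_identical(v, c("positive", "negative", "positive", "NA"))
  # "No" and empty both mean no drugs
  pr$cm02_drugs <- "No"
  expect_identical(prior_layers(pr)[[1]]$verdict, "negative")
  pr$cm02_drugs <- ""
  expect_identical(prior_layers(pr)[[1]]$verdict, "negative")
})

test_that("driver-correlation layer ranks the focal CRF", {
  b <- simulate_cohort(n_samples = 200, n_genes = 500, delta = 2, seed = 17,
                       n_decoy_sets = 3)
  fit <- suppressMessages(discover_oncomodules(
    b$expression, b$mutations, b$registry, b$gene_sets, "CRF1"))
  skip_if(!b$truth$planted_set %in% names(fit$modules))
  z <- fit$slea[paste0(b$truth$planted_set, "_up"), ]
  lay <- driver_correlation_layer(z, b$mutations, b$registry, "CRF1")
  expect_identical(lay$verdict, "positive")
  expect_identical(lay$detail$driver[1], "CRF1")
  expect_true(all(lay$detail$n_mutated >= 5))

  # a module driven by a different driver is disqualified
  alt <- b$registry$gene[b$registry$is_driver & !b$registry$is_crf][1]
  alt_samples <- unique(b$mutations$sample[b$mutations$gene == alt])
  z2 <- setNames(as.numeric(names(z) %in% alt_samples) * 3 +
                   rnorm(length(z), 0, 0.1), names(z))
  lay2 <- driver_correlation_layer(z2, b$mutations, b$registry, "CRF1")
  expect_identical(lay2$verdict, "disqualify")
  expect_false(lay2$detail$driver[1] == "CRF1")

  # focal CRF below the eligibility floor is a misconfiguration
  expect_error(
    driver_correlation_layer(z, b$mutations, b$registry, "CRF1",
                             min_mutated = 10000),
    "fewer than")

  # single eligible driver: trivially rank 1
  reg1 <- driver_registry("CRF1", TRUE, TRUE, "LoF")
  lay3 <- driver_correlation_layer(z, b$mutations, reg1, "CRF1")
  expect_identical(lay3$verdict, "positive")
  expect_identical(nrow(lay3$detail), 1L)
})

test_that("cell-line layer verdicts: positive, negative, NA", {
  up <- sprintf("G%05d", 1:20); down <- sprintf("G%05d", 21:40)
  mod <- structure(list(name = "M", collection = "c",
                        category = "tf_targets", controller = "TF",
                        up_set = up, down_set = down),
                   class = "oncomodule")
  pos_panel <- simulate_cell_lines(10, 10, 500, up, down, "CRF1",
                                   delta = 3, seed = 2)
  expect_identical(
    cellline_layer(pos_panel, mod, "CRF1", "tissueA")$verdict, "positive")

  null_panel <- simulate_cell_lines(10, 10, 500, up, down, "CRF1",
                                    delta = 0, seed = 2)
  expect_identical(
    cellline_layer(null_panel, mod, "CRF1", "tissueA")$verdict, "negative")

  # mutation status not assayed -> NA (the unassayable-CRF case)
  blind <- simulate_cell_lines(10, 10, 500, up, down, "CRF1", delta = 3,
                               include_focal_status = FALSE, seed = 2)
  expect_identical(
    cellline_layer(blind, mod, "CRF1", "tissueA")$verdict, "NA")

  # discordant shift is not rewarded: planted downward on the up-subset
  flip_panel <- simulate_cell_lines(10, 10, 500, up_genes = down,
                                    down_genes = up, "CRF1", delta = 3,
                                    seed = 2)
  expect_identical(
    cellline_layer(flip_panel, mod, "CRF1", "tissueA")$verdict, "negative")

  expect_error(cellline_layer(pos_panel, mod, "CRF1", "nope"),
               "unknown tissue")
})

test_that("extreme gene sets: idempotence, tails, expectation", {
  set.seed(31)
  z <- setNames(rnorm(1000), sprintf("G%04d", 1:1000))
  # two identical experiments reduce to one experiment's extreme set
  ex2 <- extreme_gene_set(list(z, z), q = 0.025, min_experiments = 2)
  ord <- order(z)
  single <- sort(c(names(z)[ord[1:25]], names(z)[ord[976:1000]]))
  expect_identical(ex2, single)
  expect_length(ex2, 50)

  # disjoint extremes -> empty consensus
  z2 <- z; z2[single] <- 0
  expect_length(extreme_gene_set(list(z, z2), 0.025, 2), 0)

  # independent experiments: expected consensus size ~ N * (2q)^2 = 2.5
  sizes <- vapply(1:60, function(i) {
    set.seed(i)
    e1 <- setNames(rnorm(1000), names(z))
    e2 <- setNames(rnorm(1000), names(z))
    length(extreme_gene_set(list(e1, e2), 0.025, 2))
  }, numeric(1))
  expect_lt(abs(mean(sizes) - 2.5), 1)

  # below the experiment floor: NULL as the caller's NA signal
  expect_null(extreme_gene_set(list(z), 0.025, 2))
})

test_that("knock-down overlap layer matches the Fisher oracle", {
  kd <- simulate_kd_experiments(c("CRF1", "TF1"), n_experiments = 2,
                                n_universe = 1000, rho = 0.5, seed = 6)
  lay <- knockdown_overlap_layer(kd, "CRF1", "TF1")
  expect_identical(lay$verdict, "positive")
  d <- lay$detail
  expect_equal(d$p, oracle_fisher_greater(d$in_both, d$focal_only,
                                          d$controller_only, d$neither),
               tolerance = 1e-9)
  expect_lt(d$p, 1e-6)

  # no controller (pathway module) -> NA
  expect_identical(knockdown_overlap_layer(kd, "CRF1", NA)$verdict, "NA")
  # missing experiments -> NA
  expect_identical(knockdown_overlap_layer(kd, "CRF1", "ABSENT")$verdict,
                   "NA")

  # fixed table [10, 15; 15, 960] against the oracle
  fake <- structure(list(
    universe = sprintf("G%04d", 1:1000),
    experiments = list()), class = "kd_catalog")
  p_oracle <- oracle_fisher_greater(10, 15, 15, 960)
  got <- fisher.test(matrix(c(10, 15, 15, 960), 2, 2, byrow = TRUE),
                     alternative = "greater")$p.value
  expect_equal(got, p_oracle, tolerance = 1e-10)
})

test_that("score_oncomodules assembles a full scorecard table", {
  b <- simulate_cohort(n_samples = 200, n_genes = 500, delta = 2, seed = 23,
                       n_decoy_sets = 3)
  fit <- suppressMessages(discover_oncomodules(
    b$expression, b$mutations, b$registry, b$gene_sets, "CRF1"))
  skip_if(!b$truth$planted_set %in% names(fit$modules))
  panel <- simulate_cell_lines(10, 10, 500,
                               fit$modules[[b$truth$planted_set]]$up_set,
                               fit$modules[[b$truth$planted_set]]$down_set,
                               "CRF1", delta = 3, seed = 2)
  kd <- simulate_kd_experiments(c("CRF1", b$truth$controller),
                                n_universe = 1000, rho = 0.5, seed = 4)
  priors <- data.frame(module = b$truth$planted_set,
                       cm02_drugs = "rapamycin", prior_crf = TRUE,
                       prior_tumor = TRUE, prior_cancer = TRUE)
  sc <- score_oncomodules(fit$modules, fit$slea, b$mutations, b$registry,
                          "CRF1", priors = priors, panel = panel,
                          tissue = "tissueA", kd = kd)
  row <- sc[sc$module == b$truth$planted_set, ]
  expect_identical(row$driver_correlation, "positive")
  expect_identical(row$cm02, "positive")
  expect_identical(row$cellline, "positive")
  expect_identical(row$kd_overlap, "positive")
  expect_identical(row$overall, "7/7")
})
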