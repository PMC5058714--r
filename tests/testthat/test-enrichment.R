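test_that("hypergeometric tail matches direct enumeration", {
  expect_identical(hypergeometric_tail(0, 5, 4, 10), 1)
  # C(4,4) * C(6,1) / C(10,5) = 6/252
  expect_equal(hypergeometric_tail(4, 5, 4, 10), 6 / 252, tolerance = 1e-12)
  expect_error(hypergeometric_tail(5, 4, 4, 10), "inconsistent")

  # full grid up to universe 25 against the choose() oracle
  for (N in c(3, 7, 12, 18, 25)) {
    for (t in 0:N) for (q in 0:N) for (k in 0:min(t, q)) {
      expect_equal(hypergeometric_tail(k, q, t, N),
                   oracle_hyper_tail(k, q, t, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("collection enrichment intersects with the universe and uses BH", {
  universe <- paste0("G", 1:100)
  de <- paste0("G", 1:10)
  col <- gene_set_collection("c", "pathway", list(
    HIT = de,                              # equals the DE set
    MISS = paste0("G", 60:70),             # disjoint from DE
    OUT = c(paste0("G", 5:8), "ZZZ")))     # partially outside the universe
  tab <- enrich_collection(de, col, universe)
  expect_identical(tab$term[tab$set == "OUT"], 4L)   # ZZZ dropped
  expect_identical(tab$overlap[tab$set == "HIT"], 10L)
  expect_equal(tab$raw_p[tab$set == "HIT"],
               oracle_hyper_tail(10, 10, 10, 100), tolerance = 1e-12)
  expect_true(tab$significant[tab$set == "HIT"])
  expect_false(tab$significant[tab$set == "MISS"])
  expect_equal(tab$adj_p, oracle_bh(tab$raw_p), tolerance = 1e-12)

  # permuting set order leaves adjusted p-values unchanged
  col2 <- gene_set_collection("c", "pathway", rev(col$sets))
  tab2 <- enrich_collection(de, col2, universe)
  expect_equal(tab2$adj_p[match(tab$set, tab2$set)], tab$adj_p)

  # relabeling genes leaves the p-values unchanged (only counts matter)
  relab <- setNames(paste0("H", 1:100), universe)
  col3 <- gene_set_collection("c", "pathway",
                              lapply(col$sets, function(s)
                                unname(relab[intersect(s, universe)])))
  tab3 <- enrich_collection(unname(relab[de]), col3, unname(relab))
  expect_equal(tab3$raw_p[match(tab$set, tab3$set)], tab$raw_p,
               tolerance = 1e-12)

  expect_error(enrich_collection(de, col, character()), "empty universe")
  expect_error(enrich_collection(c(de, "NOT_THERE"), col, universe),
               "outside the universe")
})

test_that("oncomodule assembly applies the raw-p add-back rule", {
  # 12-gene set: 8 adjusted-significant, 4 raw-only-significant, plus 3
  # set members above the raw cutoff
  genes <- paste0("G", 1:40)
  raw <- rep(0.8, 40)
  raw[1:8] <- 1e-4          # DE after BH
  raw[9:12] <- 0.03         # raw-significant only
  adj <- p.adjust(raw, "BH")
  det <- structure(data.frame(
    gene = genes, statistic = 0, raw_p = raw, adj_p = adj,
    direction = rep(c("up", "down"), 20), de_flag = adj < 0.05,
    stringsAsFactors = FALSE), class = c("de_table", "data.frame"))
  col <- gene_set_collection("tf", "tf_targets",
                             list(M1 = paste0("G", 1:15)))
  enr <- enrich_collection(genes[det$de_flag], col, genes)
  expect_true(enr$significant[1])
  mods <- assemble_oncomodules(enr, det, list(col))
  m <- mods$M1
  expect_length(c(m$up_set, m$down_set), 12)
  expect_length(intersect(m$up_set, m$down_set), 0)
  # add-back never removes an adjusted-significant member
  expect_true(all(intersect(genes[det$de_flag], paste0("G", 1:15)) %in%
                    c(m$up_set, m$down_set)))
  # controller inherited from the tf_targets collection
  expect_identical(m$controller, "M1")
  # direction split matches the DE table
  expect_true(all(det$direction[match(m$up_set, det$gene)] == "up"))
  expect_true(all(det$direction[match(m$down_set, det$gene)] == "down"))

  # direction-none members are dropped but logged
  det2 <- det
  det2$direction[1] <- "none"
  expect_message(mods2 <- assemble_oncomodules(enr, det2, list(col)),
                 "no direction")
  expect_length(c(mods2$M1$up_set, mods2$M1$down_set), 11)

  # pathway collections carry no controller
  colp <- gene_set_collection("kegg", "pathway", list(M1 = paste0("G", 1:15)))
  enrp <- enrich_collection(genes[det$de_flag], colp, genes)
  modp <- assemble_oncomodules(enrp, det, list(colp))
  expect_true(is.na(modp$M1$controller))
})

test_that("pooled BH scope corrects across collections", {
  universe <- paste0("G", 1:60)
  c1 <- gene_set_collection("a", "pathway", list(S1 = paste0("G", 1:6)))
  c2 <- gene_set_collection("b", "pathway", list(S2 = paste0("G", 7:12),
                                                 S3 = paste0("G", 13:18)))
  de <- paste0("G", 1:6)
  pooled <- enrich_collections(de, list(c1, c2), universe,
                               bh_scope = "pooled")
  expect_equal(pooled$adj_p, oracle_bh(pooled$raw_p), tolerance = 1e-12)
  per <- enrich_collections(de, list(c1, c2), universe,
                            bh_scope = "collection")
  expect_equal(per$adj_p[per$set == "S1"], per$raw_p[per$set == "S1"])
})
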