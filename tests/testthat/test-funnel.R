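test_that("growth-factor annotation intersects and flags an unloaded set", {
  b <- toy_bundle()
  expect_equal(annotate_factors(c("P1", "XX"), b), "P1")
  expect_equal(annotate_factors("ZZ", b), character(0))
  empty <- b
  empty$growth_factors <- character(0)
  expect_error(annotate_factors("P1", empty), "empty")
})

test_that("secretion filter combines predictors under any/all modes", {
  b <- toy_bundle()  # P1: yes/no; P2: no/no
  expect_equal(secretion_filter(c("P1", "P2"), b, mode = "any"), "P1")
  expect_equal(secretion_filter(c("P1", "P2"), b, mode = "all"), character(0))
  # missing calls default to not secreted, switchable
  expect_equal(secretion_filter("GF_EXTRA", b), character(0))
  expect_equal(secretion_filter("GF_EXTRA", b, missing_policy = "secreted"), "GF_EXTRA")
  no_pred <- b
  no_pred$secretion_calls <- no_pred$secretion_calls[0, ]
  expect_error(secretion_filter("P1", no_pred), "predictors")
})

test_that("receptor filter records matches and drop reasons", {
  b <- toy_bundle()  # P1 -> R1, expressed in AT2 only
  kept <- receptor_filter(c("P1", "P2"), b)
  expect_equal(kept$gene_symbol, "P1")
  expect_equal(kept$receptors, "R1")
  expect_equal(kept$cell_types, "AT2")
  dropped <- attr(kept, "dropped")
  expect_equal(dropped$reason[dropped$gene_symbol == "P2"], "no known receptor")

  silent <- b
  silent$receptor_expression$expressed <- FALSE
  kept2 <- receptor_filter("P1", silent)
  expect_equal(nrow(kept2), 0)
  expect_match(attr(kept2, "dropped")$reason, "not expressed")
})

test_that("the full funnel is a monotone chain with consistent provenance", {
  fx <- generate_secretome_fixture(
    secretome_fixture_config(n_proteins = 300, n_planted_candidates = 4, seed = 7))
  fr <- run_funnel(fx$table, fx$bundle)
  ss <- fr$surviving_sets
  universe <- union(ss$consistent$EV, ss$consistent$SF)
  expect_true(all(ss$consistent$EV %in% ss$identified$EV))
  expect_true(all(ss$consistent$SF %in% ss$identified$SF))
  expect_true(all(ss$growth_factors %in% universe))
  expect_true(all(ss$secreted %in% ss$growth_factors))
  expect_true(all(ss$receptor_matched %in% ss$secreted))
  # provenance agrees with the partition
  for (i in seq_len(nrow(fr$candidates))) {
    g <- fr$candidates$gene_symbol[i]
    comp <- fr$candidates$provenance[i]
    expect_true(g %in% switch(comp, EV_only = fr$partition$ev_only,
                              both = fr$partition$both,
                              SF_only = fr$partition$sf_only))
  }
  # counts equal set sizes
  sc <- fr$stage_counts
  expect_equal(sc$count[sc$stage == "growth_factors" & sc$compartment == "total"],
               length(ss$growth_factors))
})

test_that("funnel stage counts are invariant to input row order", {
  fx <- generate_secretome_fixture(
    secretome_fixture_config(n_proteins = 120, n_planted_candidates = 3, seed = 21))
  fr1 <- run_funnel(fx$table, fx$bundle)
  set.seed(5)
  shuffled <- detection_table(as.data.frame(fx$table)[sample(nrow(fx$table)), ])
  fr2 <- run_funnel(shuffled, fx$bundle)
  expect_equal(fr1$stage_counts, fr2$stage_counts)
  expect_equal(fr1$candidates, fr2$candidates)
})

test_that("an empty detection table yields an all-zero funnel", {
  empty <- detection_table(data.frame(protein_id = character(),
                                      gene_symbol = character(),
                                      fraction = character(),
                                      replicate = integer(),
                                      detected = logical()))
  fr <- run_funnel(empty, toy_bundle())
  expect_true(all(fr$stage_counts$count == 0))
  expect_equal(nrow(fr$candidates), 0)
})

test_that("marker enrichment matches the exact hypergeometric tail", {
  # toy 2x2 (8,2;2,8): compare against the exhaustively summed
  # hypergeometric two-sided p (sum of all tables at most as probable)
  markers <- sprintf("M%02d", 1:10)
  others <- sprintf("N%02d", 1:10)
  build <- function(ev, sf) {
    rows <- rbind(
      data.frame(gene = ev, fraction = "EV", stringsAsFactors = FALSE),
      data.frame(gene = sf, fraction = "SF", stringsAsFactors = FALSE))
    recs <- data.frame(protein_id = paste0(rows$gene, "_", rows$fraction, "_acc"),
                       gene_symbol = rows$gene, fraction = rows$fraction,
                       replicate = 1L, detected = TRUE, stringsAsFactors = FALSE)
    detection_table(recs)
  }
  tab <- build(c(markers[1:8], others[1:2]), c(markers[9:10], others[3:10]))
  res <- marker_enrichment(tab, markers)
  expect_equal(unname(res$counts["marker", ]), c(8, 2))
  expect_equal(unname(res$counts["non_marker", ]), c(2, 8))
  # exhaustive enumeration over k = number of EV markers given margins
  dens <- vapply(0:10, function(k) {
    choose(10, k) * choose(10, 10 - k) / choose(20, 10)
  }, numeric(1))
  p_exact <- sum(dens[dens <= dens[8 + 1] * (1 + 1e-7)])
  expect_equal(res$p_value, p_exact, tolerance = 1e-10)
  expect_gt(res$odds_ratio, 1)

  # markers only in EV: infinite-odds sentinel with corrected estimate
  tab2 <- build(c(markers[1:5], others[1:3]), others[4:8])
  res2 <- marker_enrichment(tab2, markers)
  expect_identical(unname(res2$odds_ratio), Inf)
  expect_true(res2$continuity_corrected)
  expect_true(is.finite(res2$odds_ratio_corrected))

  # identical marker composition in both fractions: odds ratio 1
  tab3 <- build(c(markers[1:4], others[1:4]), c(markers[1:4], others[1:4]))
  res3 <- marker_enrichment(tab3, markers)
  expect_equal(unname(res3$odds_ratio), 1, tolerance = 1e-8)
  expect_error(marker_enrichment(tab3, character(0)), "non-empty")
})
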