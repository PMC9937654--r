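test_that("session averages impute zeros and only zeros", {
  expect_equal(session_mean(c(0, 0)), 0.5)
  expect_equal(session_mean(c(1, 0)), 0.5)  # plain mean equals the floor
  expect_equal(session_mean(c(4, 6)), 5.0)
  expect_equal(session_mean(0), 0.5)
  expect_error(session_mean(numeric(0)), "at least one")
  expect_error(session_mean(c(-1, 2)), "non-negative")
})

test_that("fold change is the plain ratio of positive session means", {
  expect_equal(session_fold_change(5.0, 0.5), 10.0)
  expect_equal(session_fold_change(3.2, 3.2), 1.0)
  expect_equal(session_fold_change(0.5, 10), 0.05)
  expect_error(session_fold_change(0, 1), "positive")
  expect_error(session_fold_change(1, 0), "positive")
})

test_that("session fold changes combine by an unweighted symmetric mean", {
  expect_equal(combine_sessions(c(2.0, 4.0)), 3.0)
  expect_equal(combine_sessions(7.3), 7.3)  # single-session datasets pass through
  expect_equal(combine_sessions(c(4.0, 2.0)), combine_sessions(c(2.0, 4.0)))
  expect_error(combine_sessions(numeric(0)), "at least one")
})

test_that("contaminant filtering honors lists and the keep_mito switch", {
  tab <- toy_count_table(list(
    P1 = list(TDTOMATO = c(1, 1, 1, 1)),
    P2 = list(TDTOMATO = c(2, 2, 2, 2)),
    P3 = list(TDTOMATO = c(3, 3, 3, 3)),
    PC = list(TDTOMATO = c(9, 9, 9, 9)),
    MT1 = list(TDTOMATO = c(4, 4, 4, 4))))
  mito <- gene_list("mito", "Mt1")
  cont <- gene_list("cont", c("Pc", "Pcca"))
  filt <- filter_contaminants(tab, mito, cont)
  expect_setequal(unique(filt$gene_symbol), c("P1", "P2", "P3"))
  kept <- filter_contaminants(tab, mito, cont, keep_mito = TRUE)
  expect_setequal(unique(kept$gene_symbol), c("P1", "P2", "P3", "MT1"))
  log <- attr(filt, "filter_log")
  expect_setequal(log$gene_symbol, c("PC", "MT1"))
  expect_equal(sum(log$n_records), 8)
})

test_that("a worked single-protein table yields the forced fold change", {
  tab <- toy_count_table(list(
    P1 = list(RIM_PPCP = c(2, 2, 2, 2), TDTOMATO = c(1, 1, 1, 1))))
  res <- run_enrichment(tab)
  row <- res[res$bait == "RIM_PPCP", ]
  expect_equal(row$mean_fc, 2.0)
  expect_equal(row$log2_fc, 1.0)
  expect_equal(row$session_fc[[1]], c(2, 2))
  expect_true(row$hit_2)
  # threshold is inclusive: exactly 2.0-fold is a hit
  expect_true("P1" %in% call_hits(res, 2.0)$per_bait$RIM_PPCP)
  expect_false("P1" %in% call_hits(res, 2.0000001)$per_bait$RIM_PPCP)
})

test_that("a missing reference block imputes to 0.5 in the denominator", {
  tab <- toy_count_table(list(
    P1 = list(RIM_PPCP = c(4, 6, 4, 6), TDTOMATO = c(1, 1, 1, 1)),
    P2 = list(RIM_PPCP = c(4, 6, 4, 6))))
  res <- run_enrichment(tab)
  expect_equal(res$mean_fc[res$protein_id == "P2" &
                             res$bait == "RIM_PPCP"], 10)
})

test_that("proteins detected only in the reference appear as depleted", {
  tab <- toy_count_table(list(
    P1 = list(RIM_PPCP = c(1, 1, 1, 1), TDTOMATO = c(1, 1, 1, 1)),
    P2 = list(TDTOMATO = c(10, 10, 10, 10))))
  res <- run_enrichment(tab)
  expect_equal(res$mean_fc[res$protein_id == "P2"], 0.05)
})

test_that("hit sets are nested across thresholds on simulated data", {
  cfg <- sim_config(n_proteins = 300, seed = 11)
  res <- sim_hits(cfg)$res
  h15 <- call_hits(res, 1.5)$union
  h20 <- call_hits(res, 2.0)$union
  h25 <- call_hits(res, 2.5)$union
  expect_true(all(h25 %in% h20))
  expect_true(all(h20 %in% h15))
  expect_true(length(h25) <= length(h20) && length(h20) <= length(h15))
})

test_that("rescaling one whole session leaves its fold changes unchanged", {
  tab <- toy_count_table(list(
    P1 = list(RIM_PPCP = c(4, 6, 3, 5), ELKS2B = c(2, 2, 2, 2),
              CAVB4 = c(1, 2, 3, 4), TDTOMATO = c(2, 3, 4, 5)),
    P2 = list(RIM_PPCP = c(8, 8, 8, 8), ELKS2B = c(5, 5, 5, 5),
              CAVB4 = c(3, 3, 3, 3), TDTOMATO = c(4, 4, 4, 4))))
  scaled <- tibble::as_tibble(tab)
  s1 <- scaled$session == 1
  scaled$peptide_count[s1] <- scaled$peptide_count[s1] * 3L
  res0 <- run_enrichment(tab)
  res1 <- run_enrichment(count_table(scaled))
  expect_equal(res1$session_fc, res0$session_fc, tolerance = 1e-12)
  expect_equal(res1$mean_fc, res0$mean_fc, tolerance = 1e-12)
})

test_that("results do not depend on row or repeat ordering", {
  cfg <- sim_config(n_proteins = 120, seed = 5)
  sim <- simulate_dataset(cfg)
  tab <- sim$counts
  perm <- withr::with_seed(3, sample(nrow(tab)))
  res0 <- run_enrichment(tab)
  res1 <- run_enrichment(count_table(tibble::as_tibble(tab)[perm, ]))
  expect_equal(tibble::as_tibble(res0), tibble::as_tibble(res1))
})

test_that("every session fold change is finite and positive", {
  cfg <- sim_config(n_proteins = 200, dropout_prob = 0.3, seed = 21)
  res <- sim_hits(cfg)$res
  fcs <- unlist(res$session_fc)
  expect_true(all(is.finite(fcs) & fcs > 0))
})

test_that("per-bait identification counts follow the summary definitions", {
  cfg <- sim_config(n_proteins = 200, seed = 9)
  res <- sim_hits(cfg)$res
  summ <- enrichment_summary(res)
  for (b in summ$bait) {
    sub <- res[res$bait == b, ]
    expect_equal(summ$n_identified[summ$bait == b], nrow(sub))
    expect_equal(summ$n_positive[summ$bait == b], sum(sub$log2_fc > 0))
    expect_equal(summ$n_hits[summ$bait == b], sum(sub$mean_fc >= 2))
    expect_true(summ$n_hits[summ$bait == b] <=
                  summ$n_positive[summ$bait == b])
  }
})

test_that("multi-genotype tables are rejected by run_enrichment", {
  tab1 <- toy_count_table(list(P1 = list(TDTOMATO = c(1, 1, 1, 1))))
  tab2 <- toy_count_table(list(P1 = list(TDTOMATO = c(1, 1, 1, 1))),
                          genotype = "RIM_CKO")
  both <- count_table(dplyr::bind_rows(tibble::as_tibble(tab1),
                                       tibble::as_tibble(tab2)))
  expect_error(run_enrichment(both), "single genotype")
})
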