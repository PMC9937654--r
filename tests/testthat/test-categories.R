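test_that("factorial F statistics match the sums-of-squares oracle", {
  for (i in 1:20) {
    na <- sample(2:4, 1); nb <- sample(2:3, 1); r <- sample(3:10, 1)
    df <- balanced_design(na, nb, r, seed = 100 + i,
                          delta = runif(1, 0, 2))
    fit <- two_way_anova_bonferroni(df)
    oracle <- anova_balanced_oracle(df)
    expect_lt(abs(fit$anova$F[fit$anova$term == "genotype"] -
                    oracle$F_genotype), 1e-8)
    expect_lt(abs(fit$anova$F[fit$anova$term == "bait"] -
                    oracle$F_bait), 1e-8)
    expect_lt(abs(fit$anova$F[fit$anova$term == "interaction"] -
                    oracle$F_interaction), 1e-8)
  }
})

test_that("a planted cell shift shows up in the interaction term", {
  df <- balanced_design(2, 2, 20, seed = 55, delta = 3)
  fit <- two_way_anova_bonferroni(df)
  expect_lt(fit$anova$p[fit$anova$term == "interaction"], 0.01)
})

test_that("degenerate inputs are rejected", {
  flat <- tibble::tibble(value = rep(1, 12),
                         genotype = rep(c("A", "B"), 6),
                         bait = rep(c("X", "Y"), each = 6))
  expect_error(two_way_anova_bonferroni(flat), "zero total variance")
  one_level <- tibble::tibble(value = rnorm(6), genotype = "A",
                              bait = rep(c("X", "Y"), 3))
  expect_error(two_way_anova_bonferroni(one_level), "two levels")
})

test_that("post-hoc p-values are Bonferroni-multiplied and capped", {
  df <- balanced_design(3, 3, 6, seed = 77)
  df$genotype[df$genotype == "G1"] <- "CONTROL"
  fit <- two_way_anova_bonferroni(df)
  n_comp <- sum(!fit$posthoc$skipped)
  expect_equal(n_comp, 6)  # 2 mutants x 3 baits
  expect_equal(fit$posthoc$p_adj,
               pmin(fit$posthoc$p_raw * n_comp, 1))
  expect_true(all(fit$posthoc$p_adj <= 1))
  # a raw p of 0.01 under 6 comparisons adjusts to 0.06
  expect_equal(min(0.01 * n_comp, 1), 0.06)
})

test_that("unequal cells skip the affected comparison with a flag", {
  df <- balanced_design(2, 2, 4, seed = 78)
  df$genotype[df$genotype == "G1"] <- "CONTROL"
  df <- df[!(df$genotype == "G2" & df$bait == "B2"), ]
  df <- dplyr::bind_rows(df, tibble::tibble(
    value = 0.1, genotype = "G2", bait = "B2"))
  fit <- two_way_anova_bonferroni(df)
  expect_true(fit$posthoc$skipped[fit$posthoc$bait == "B2"])
  expect_false(fit$posthoc$skipped[fit$posthoc$bait == "B1"])
})

test_that("category means and SEMs follow the sample formulas", {
  res <- local({
    df <- tibble::tibble(
      protein_id = c("A", "B", "C"), gene_symbol = c("A", "B", "C"),
      bait = "RIM_PPCP", mean_fc = 2^c(1, 0, -1))
    df <- dplyr::bind_rows(df, dplyr::mutate(df, bait = "ELKS2B"),
                           dplyr::mutate(df, bait = "CAVB4"))
    df$session_fc <- lapply(df$mean_fc, identity)
    df$log2_fc <- log2(df$mean_fc)
    attr(df, "genotype") <- "CONTROL"
    class(df) <- c("enrichment_result", class(tibble::tibble()))
    df
  })
  ann <- annotation_table(tibble::tibble(
    gene_symbol = c("A", "B", "C"), path = "synapse"))
  cs <- category_mean_log2fc(res, ann, "synapse")
  row <- cs$rows[cs$rows$bait == "RIM_PPCP", ]
  expect_equal(row$mean_log2fc, 0)
  expect_equal(row$sem, sd(c(1, 0, -1)) / sqrt(3))
  expect_equal(row$n, 3L)
})

test_that("self-bait exclusion drops the bait gene from its own bait only", {
  res <- local({
    df <- tidyr::expand_grid(
      gene_symbol = c("RIMS1", "OTHER"),
      bait = c("RIM_PPCP", "ELKS2B", "CAVB4"))
    df$protein_id <- df$gene_symbol
    df$mean_fc <- 2
    df$session_fc <- lapply(df$mean_fc, identity)
    df$log2_fc <- 1
    attr(df, "genotype") <- "CONTROL"
    class(df) <- c("enrichment_result", class(tibble::tibble()))
    df
  })
  ann <- annotation_table(tibble::tibble(
    gene_symbol = c("RIMS1", "OTHER"), path = "synapse"))
  cs <- category_mean_log2fc(res, ann, "synapse", exclude_self_bait = TRUE)
  expect_equal(cs$rows$n[cs$rows$bait == "RIM_PPCP"], 1L)
  expect_equal(cs$rows$n[cs$rows$bait == "ELKS2B"], 2L)
  cs2 <- category_mean_log2fc(res, ann, "synapse",
                              exclude_self_bait = FALSE)
  expect_equal(cs2$rows$n[cs2$rows$bait == "RIM_PPCP"], 2L)
})

test_that("knockout collapse lowers planted-category means in mutants", {
  cfg <- sim_config(n_proteins = 400, seed = 91)
  panel <- simulate_genotype_panel(cfg)
  results <- lapply(panel, function(p) {
    gl <- sim_gene_lists(p$truth)
    run_enrichment(filter_contaminants(p$counts, gl$mito,
                                       gl$contaminants))
  })
  rs <- panel$CONTROL$truth$gene_symbol[panel$CONTROL$truth$is_release_site]
  ann <- annotation_table(tibble::tibble(gene_symbol = rs,
                                         path = "synapse/presynapse"))
  cs <- category_mean_log2fc(results, ann, "synapse/presynapse")
  rows <- cs$rows
  for (b in c("ELKS2B", "CAVB4")) {
    expect_lt(rows$mean_log2fc[rows$genotype == "RIM_CKO" & rows$bait == b],
              rows$mean_log2fc[rows$genotype == "CONTROL" & rows$bait == b])
  }
  expect_s3_class(cs$anova, "tbl_df")
  expect_lt(cs$anova$p[cs$anova$term == "genotype"], 0.05)
})
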