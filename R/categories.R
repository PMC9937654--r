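#' Per-category mean log2 fold change across baits and genotypes
#'
#' For every (genotype, bait) cell, averages the log2 fold change of
#' all detected proteins annotated at or below an ontology category
#' level — all identified proteins, not only hits. With
#' `exclude_self_bait` the bait-encoding gene is dropped from its own
#' bait condition only (self-biotinylation would otherwise inflate that
#' cell), but kept in the other baits. When more than one genotype is
#' supplied, a two-way factorial ANOVA (genotype x bait) with Bonferroni
#' post-hoc genotype-vs-control comparisons is run on the per-protein
#' observations.
#'
#' @param results A single [run_enrichment()] result or a list of them
#'   (one per genotype).
#' @param ann An [annotation_table()].
#' @param level Category path prefix, e.g. `"synapse/presynapse"`.
#' @param exclude_self_bait Drop each bait's own gene from its own
#'   condition (default `TRUE`).
#'
#' @return A list of class `category_summary`: `level`, `rows` (tibble
#'   genotype, bait, mean_log2fc, sem, n; `n = 0` rows carry `NA`
#'   means), `observations` (per-protein tibble), and — when at least
#'   two genotypes are present — `anova` and `posthoc` from
#'   [two_way_anova_bonferroni()].
#' @export
category_mean_log2fc <- function(results, ann, level,
                                 exclude_self_bait = TRUE) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1),
                       "enrichment_result")))
  genes <- annotated_genes(ann, level)

  obs <- dplyr::bind_rows(lapply(results, function(res) {
    sub <- tibble::as_tibble(res)
    sub <- sub[sub$gene_symbol %in% genes, ]
    if (exclude_self_bait) {
      self <- sub$gene_symbol == BAIT_GENES[sub$bait]
      sub <- sub[!self, ]
    }
    tibble::tibble(genotype = attr(res, "genotype"),
                   bait = sub$bait,
                   gene_symbol = sub$gene_symbol,
                   value = sub$log2_fc)
  }))

  cells <- tidyr::expand_grid(
    genotype = unique(obs$genotype %||% character(0)),
    bait = BAITS)
  rows <- dplyr::summarise(
    dplyr::group_by(obs, .data$genotype, .data$bait),
    mean_log2fc = mean(.data$value),
    sem = sd(.data$value) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop")
  rows <- dplyr::left_join(cells, rows, by = c("genotype", "bait"))
  rows$n[is.na(rows$n)] <- 0L

  out <- list(level = normalize_category_path(level), rows = rows,
              observations = obs)
  if (length(unique(obs$genotype)) >= 2 &&
      length(unique(obs$bait)) >= 2) {
    out <- c(out, two_way_anova_bonferroni(obs))
  }
  structure(out, class = "category_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-way factorial ANOVA with Bonferroni post-hoc tests
#'
#' Fits `value ~ genotype * bait` and reports F and p for the genotype
#' and bait main effects and their interaction, using Type-II sums of
#' squares (equal to the classical decomposition on balanced data, and
#' a deterministic, order-invariant choice on unbalanced data). Post-hoc
#' comparisons are per-bait two-sample pooled-variance t-tests of each
#' non-control genotype against `CONTROL`, with p-values multiplied by
#' the number of comparisons actually performed (capped at 1).
#'
#' @param obs Data frame with columns `value`, `genotype`, `bait`.
#'
#' @return List: `anova` (tibble term, df, F, p), `posthoc` (tibble
#'   bait, genotype, estimate, t, df, p_raw, p_adj, skipped), and
#'   `ss_type = "II"`.
#' @export
two_way_anova_bonferroni <- function(obs) {
  obs <- tibble::as_tibble(obs)[c("value", "genotype", "bait")]
  obs <- obs[complete.cases(obs), ]
  obs$genotype <- factor(obs$genotype)
  obs$bait <- factor(obs$bait)
  if (nlevels(obs$genotype) < 2 || nlevels(obs$bait) < 2) {
    stop("two-way ANOVA needs at least two levels per factor",
         call. = FALSE)
  }
  if (isTRUE(all.equal(var(obs$value), 0)) || var(obs$value) == 0) {
    stop("degenerate data: zero total variance", call. = FALSE)
  }
  fit <- lm(value ~ genotype * bait, data = obs)
  aov_tab <- car::Anova(fit, type = 2)
  terms <- c("genotype", "bait", "genotype:bait")
  anova_tbl <- tibble::tibble(
    term = c("genotype", "bait", "interaction"),
    df = aov_tab[terms, "Df"],
    F = aov_tab[terms, "F value"],
    p = aov_tab[terms, "Pr(>F)"])

  mutants <- setdiff(levels(obs$genotype), "CONTROL")
  ph <- list()
  for (b in levels(obs$bait)) {
    for (g in mutants) {
      x <- obs$value[obs$bait == b & obs$genotype == "CONTROL"]
      y <- obs$value[obs$bait == b & obs$genotype == g]
      if (length(x) < 2 || length(y) < 2) {
        ph[[length(ph) + 1]] <- tibble::tibble(
          bait = b, genotype = g, estimate = NA_real_, t = NA_real_,
          df = NA_real_, p_raw = NA_real_, skipped = TRUE)
      } else {
        tt <- t.test(y, x, var.equal = TRUE)
        ph[[length(ph) + 1]] <- tibble::tibble(
          bait = b, genotype = g,
          estimate = unname(diff(rev(tt$estimate))),
          t = unname(tt$statistic), df = unname(tt$parameter),
          p_raw = tt$p.value, skipped = FALSE)
      }
    }
  }
  posthoc <- dplyr::bind_rows(ph)
  n_comp <- sum(!posthoc$skipped)
  posthoc$p_adj <- pmin(posthoc$p_raw * n_comp, 1)
  list(anova = anova_tbl, posthoc = posthoc, ss_type = "II")
}

#' Curated gene-panel enrichment report
#'
#' Reports, for each gene of a curated panel (e.g. genes associated
#' with monogenic Parkinson's disease), the final fold change and hit
#' status in every bait and genotype. Panel genes absent from a dataset
#' are reported as not detected rather than with a fold change.
#'
#' @param results Named list of [run_enrichment()] results (names are
#'   ignored; genotypes are read from the results).
#' @param panel A [gene_list()] of panel genes.
#' @param threshold Hit threshold (default 2.0).
#'
#' @return Tibble with columns `gene_symbol`, `genotype`, `bait`,
#'   `detected`, `mean_fc`, `log2_fc`, `hit`.
#' @export
panel_report <- function(results, panel, threshold = 2.0) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  dplyr::bind_rows(lapply(results, function(res) {
    grid <- tidyr::expand_grid(gene_symbol = panel$symbols, bait = BAITS)
    sub <- tibble::as_tibble(res)[c("gene_symbol", "bait", "mean_fc",
                                    "log2_fc")]
    out <- dplyr::left_join(grid, sub, by = c("gene_symbol", "bait"))
    out$genotype <- attr(res, "genotype")
    out$detected <- !is.na(out$mean_fc)
    out$hit <- !is.na(out$mean_fc) & out$mean_fc >= threshold
    out[c("gene_symbol", "genotype", "bait", "detected", "mean_fc",
          "log2_fc", "hit")]
  }))
}
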