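#' Remove mitochondrial and purification-contaminant proteins
#'
#' Drops every record whose gene symbol appears in the mitochondrial
#' removal list (a MitoCarta-style export) or in the contaminant list
#' (pyruvate carboxylase, PCCA, neutravidin, IgGs). Mitochondrial
#' removal can be skipped (`keep_mito = TRUE`) for analyses that
#' intentionally retain mitochondrial background, e.g. overall-proteome
#' comparisons and curated-panel reports.
#'
#' @param table A [count_table()].
#' @param mito A [gene_list()] of mitochondrial genes (may be empty).
#' @param contaminants A [gene_list()] of contaminant genes.
#' @param keep_mito If `TRUE`, skip mitochondrial removal.
#'
#' @return A filtered [count_table()]; the attribute `"filter_log"`
#'   records, per removed symbol, which list matched it and how many
#'   records were dropped.
#' @export
filter_contaminants <- function(table, mito, contaminants,
                                keep_mito = FALSE) {
  stopifnot(inherits(table, "count_table"))
  drop_sets <- list()
  if (!keep_mito && length(mito$symbols) > 0) {
    drop_sets[[mito$name]] <- mito$symbols
  }
  if (length(contaminants$symbols) > 0) {
    drop_sets[[contaminants$name]] <- contaminants$symbols
  }
  log <- tibble::tibble(list = character(), gene_symbol = character(),
                        n_records = integer())
  keep <- rep(TRUE, nrow(table))
  for (nm in names(drop_sets)) {
    hit <- table$gene_symbol %in% drop_sets[[nm]] & keep
    if (any(hit)) {
      tab <- table(table$gene_symbol[hit])
      log <- dplyr::bind_rows(log, tibble::tibble(
        list = nm, gene_symbol = names(tab),
        n_records = as.integer(tab)))
    }
    keep <- keep & !hit
  }
  out <- count_table(table[keep, ], require_reference = FALSE)
  attr(out, "filter_log") <- log
  out
}

#' Session-average peptide count with pseudocount imputation
#'
#' Averages the peptide counts of the repeats acquired within one
#' mass-spectrometry session. A session average of exactly zero is
#' assigned the value 0.5, so ratios and logs are always defined; the
#' imputation floor also means a protein must be detected more than once
#' with a single peptide for its session average to exceed the floor.
#'
#' @param counts Non-negative integer vector, one entry per repeat in
#'   the session (absent repeats must be entered as 0).
#' @param imputation Value assigned to a zero session average.
#'
#' @return Positive scalar session average.
#' @export
session_mean <- function(counts, imputation = 0.5) {
  if (length(counts) == 0) {
    stop("session_mean needs at least one repeat", call. = FALSE)
  }
  if (any(!is.finite(counts) | counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  m <- mean(counts)
  if (m == 0) imputation else m
}

#' Fold change of a bait session average over the reference
#'
#' @param bait_mean,reference_mean Positive session averages from
#'   [session_mean()].
#' @return Positive scalar ratio `bait_mean / reference_mean`.
#' @export
session_fold_change <- function(bait_mean, reference_mean) {
  if (any(bait_mean <= 0) || any(reference_mean <= 0)) {
    stop("session means must be positive (imputation was skipped upstream)",
         call. = FALSE)
  }
  bait_mean / reference_mean
}

#' Average session fold changes into a final fold change
#'
#' Sessions are weighted equally regardless of their repeat counts; a
#' single-session dataset returns its sole fold change unchanged.
#'
#' @param session_fcs Numeric vector of per-session fold changes (> 0).
#' @return Positive scalar final fold change.
#' @export
combine_sessions <- function(session_fcs) {
  if (length(session_fcs) == 0) {
    stop("combine_sessions needs at least one session fold change",
         call. = FALSE)
  }
  if (any(!is.finite(session_fcs) | session_fcs <= 0)) {
    stop("session fold changes must be positive and finite",
         call. = FALSE)
  }
  mean(session_fcs)
}

#' Run the fold-change enrichment analysis
#'
#' For every detected protein and each release-site bait: average
#' peptide counts per session (with 0.5 imputation of zero averages),
#' divide by the reference-condition session average, average the
#' resulting fold changes across sessions, and take log2. A protein
#' enters the result for a given bait if it was detected (at least one
#' peptide, in any session or repeat) in that bait or in the reference;
#' proteins undetected across all conditions are excluded.
#'
#' @param table A [count_table()] restricted to a single genotype,
#'   already filtered with [filter_contaminants()] if desired.
#' @param thresholds Enrichment thresholds at which hit flags are
#'   precomputed (inclusive, `mean_fc >= t`).
#' @param imputation Pseudocount assigned to zero session averages.
#'
#' @return A tibble of class `enrichment_result` with one row per
#'   detected (protein, bait): `protein_id`, `gene_symbol`, `bait`,
#'   `session_fc` (list-column, one fold change per session), `mean_fc`,
#'   `log2_fc`, and one logical `hit_<t>` column per threshold.
#'   Attributes: `genotype`, `sessions`, `thresholds`, `provenance`
#'   (imputation constant, number of imputed session averages, filter
#'   log if present on the input).
#' @export
run_enrichment <- function(table, thresholds = c(1.5, 2.0, 2.5),
                           imputation = 0.5) {
  stopifnot(inherits(table, "count_table"))
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  genotype <- unique(table$genotype)
  if (length(genotype) != 1) {
    stop("run_enrichment expects a single genotype; found: ",
         paste(genotype, collapse = ", "), call. = FALSE)
  }
  sessions <- sort(unique(table$session))
  # repeats that constitute each session's design (absent record = 0)
  reps_per_session <- vapply(sessions, function(s) {
    length(unique(table$replicate[table$session == s]))
  }, integer(1))
  names(reps_per_session) <- as.character(sessions)
  if (!REFERENCE %in% table$bait) {
    stop("reference condition ", REFERENCE, " missing from table",
         call. = FALSE)
  }

  totals <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table),
                    .data$protein_id, .data$gene_symbol, .data$bait,
                    .data$session),
    total = sum(.data$peptide_count), .groups = "drop")
  proteins <- dplyr::distinct(totals[, c("protein_id", "gene_symbol")])
  conditions <- intersect(ALL_CONDITIONS, unique(table$bait))
  grid <- tidyr::expand_grid(proteins, bait = conditions,
                             session = sessions)
  grid <- dplyr::left_join(grid, totals,
                           by = c("protein_id", "gene_symbol", "bait",
                                  "session"))
  grid$total[is.na(grid$total)] <- 0
  grid$n_reps <- reps_per_session[as.character(grid$session)]
  grid$sess_mean <- ifelse(grid$total == 0, imputation,
                           grid$total / grid$n_reps)
  n_imputed <- sum(grid$total == 0)

  ref <- grid[grid$bait == REFERENCE,
              c("protein_id", "session", "sess_mean")]
  names(ref)[3] <- "ref_mean"
  fc <- dplyr::left_join(grid[grid$bait != REFERENCE, ], ref,
                         by = c("protein_id", "session"))
  fc$fc_value <- session_fold_change(fc$sess_mean, fc$ref_mean)

  detected <- dplyr::summarise(
    dplyr::group_by(totals, .data$protein_id, .data$bait),
    det = sum(.data$total) > 0, .groups = "drop")
  det_ref <- detected[detected$bait == REFERENCE & detected$det,
                      "protein_id", drop = TRUE]

  fc <- fc[order(fc$protein_id, fc$bait, fc$session), ]
  res <- dplyr::summarise(
    dplyr::group_by(fc, .data$protein_id, .data$gene_symbol, .data$bait),
    session_fc = list(.data$fc_value),
    mean_fc = mean(.data$fc_value), .groups = "drop")
  res$log2_fc <- log2(res$mean_fc)

  det_bait <- detected[detected$det & detected$bait != REFERENCE, ]
  pair_key <- paste(res$protein_id, res$bait)
  keep <- res$protein_id %in% det_ref |
    pair_key %in% paste(det_bait$protein_id, det_bait$bait)
  res <- res[keep, ]

  for (t in thresholds) {
    res[[paste0("hit_", format(t))]] <- res$mean_fc >= t
  }
  res <- res[order(res$protein_id, res$bait), ]
  attr(res, "genotype") <- genotype
  attr(res, "sessions") <- sessions
  attr(res, "thresholds") <- thresholds
  attr(res, "provenance") <- list(
    imputation = imputation,
    n_imputed_session_means = n_imputed,
    filter_log = attr(table, "filter_log"))
  class(res) <- c("enrichment_result", class(tibble::tibble()))
  res
}

#' Call enriched proteins ("hits") at a threshold
#'
#' A protein is a hit for a bait if its final fold change is at least
#' the threshold (inclusive); the union set collects proteins that are
#' hits in at least one bait condition.
#'
#' @param result An [run_enrichment()] result.
#' @param threshold Positive enrichment threshold (default 2.0).
#'
#' @return List with `per_bait` (named list of protein-id vectors, one
#'   per bait), `union` (protein ids hit in >= 1 bait), and `threshold`.
#' @export
call_hits <- function(result, threshold = 2.0) {
  stopifnot(inherits(result, "enrichment_result"))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a positive number", call. = FALSE)
  }
  per_bait <- lapply(BAITS, function(b) {
    sort(result$protein_id[result$bait == b & result$mean_fc >= threshold])
  })
  names(per_bait) <- BAITS
  list(per_bait = per_bait,
       union = sort(unique(unlist(per_bait))),
       threshold = threshold)
}

#' Per-bait identification and hit counts
#'
#' Summarizes an enrichment result the way the primary histograms are
#' reported: per bait, the number of proteins identified (detected in
#' the bait or the reference), the number with log2 fold change > 0,
#' and the number of hits (fold change at or above `hit_threshold`,
#' i.e. log2 fold change >= 1 at the default 2.0).
#'
#' @param result An [run_enrichment()] result.
#' @param hit_threshold Fold-change threshold defining hits.
#' @return Tibble with columns `bait`, `n_identified`, `n_positive`,
#'   `n_hits`.
#' @export
enrichment_summary <- function(result, hit_threshold = 2.0) {
  stopifnot(inherits(result, "enrichment_result"))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(result), .data$bait),
    n_identified = dplyr::n(),
    n_positive = sum(.data$log2_fc > 0),
    n_hits = sum(.data$mean_fc >= hit_threshold),
    .groups = "drop")
}
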