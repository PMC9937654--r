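#' Write analysis results to disk
#'
#' Deterministic, sorted, round-trippable exports: enrichment results
#' and category summaries go to tab-delimited text, Venn partitions to
#' JSON (region -> members and counts). Re-reading an export reproduces
#' the exported fields exactly.
#'
#' @param x An `enrichment_result`, `venn_partition` or
#'   `category_summary`.
#' @param path Output file path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @rdname write_results
#' @export
write_results.enrichment_result <- function(x, path, ...) {
  flat <- tibble::as_tibble(x)
  sessions <- attr(x, "sessions")
  fc_mat <- do.call(rbind, flat$session_fc)
  for (i in seq_along(sessions)) {
    flat[[paste0("session_fc_", sessions[i])]] <- fc_mat[, i]
  }
  flat$session_fc <- NULL
  flat$genotype <- attr(x, "genotype")
  flat <- flat[order(flat$protein_id, flat$bait), ]
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
write_results.venn_partition <- function(x, path, ...) {
  payload <- list(
    threshold = x$threshold,
    n_union = x$n_union,
    n_multi = x$n_multi,
    n_all_three = x$n_all_three,
    regions = lapply(x$regions, as.character),
    counts = as.list(x$counts),
    max_fc = x$max_fc)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
write_results.category_summary <- function(x, path, ...) {
  rows <- x$rows
  rows$level <- x$level
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read back an exported enrichment result
#'
#' Inverse of [write_results()] for enrichment tables; restores the
#' `session_fc` list-column and result attributes.
#'
#' @param path Path written by `write_results()`.
#' @return An `enrichment_result` tibble.
#' @export
read_enrichment_result <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  fc_cols <- grep("^session_fc_", names(flat), value = TRUE)
  sessions <- as.integer(sub("^session_fc_", "", fc_cols))
  genotype <- unique(flat$genotype)
  fc_mat <- as.matrix(flat[fc_cols])
  flat$session_fc <- lapply(seq_len(nrow(flat)),
                            function(i) unname(fc_mat[i, ]))
  flat <- flat[setdiff(names(flat), c(fc_cols, "genotype"))]
  hit_cols <- grep("^hit_", names(flat), value = TRUE)
  ord <- c("protein_id", "gene_symbol", "bait", "session_fc", "mean_fc",
           "log2_fc", hit_cols)
  flat <- flat[ord]
  attr(flat, "genotype") <- genotype
  attr(flat, "sessions") <- sessions
  attr(flat, "thresholds") <- as.numeric(sub("^hit_", "", hit_cols))
  class(flat) <- c("enrichment_result", class(tibble::tibble()))
  flat
}
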