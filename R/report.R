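#' Configuration for a full analysis run
#'
#' @param counts Path to the peptide-count table (TSV).
#' @param mito,contaminants Paths to removal gene lists (plain text,
#'   one symbol per line); `mito = NULL` skips mitochondrial removal.
#' @param annotation Optional path to an annotation table (TSV).
#' @param panel Optional path to a curated gene-panel list.
#' @param thresholds Ascending distinct positive enrichment thresholds.
#' @param category_levels Category paths summarized when an annotation
#'   table is given.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the run log (the analysis
#'   itself is deterministic).
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts, mito = NULL, contaminants = NULL,
                       annotation = NULL, panel = NULL,
                       thresholds = c(1.5, 2.0, 2.5),
                       category_levels = c("synapse",
                                           "synapse/presynapse",
                                           "synapse/presynapse/active zone"),
                       out_dir, seed = 1L) {
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0)) {
    stop("thresholds must be positive, distinct and ascending",
         call. = FALSE)
  }
  structure(list(counts = counts, mito = mito,
                 contaminants = contaminants, annotation = annotation,
                 panel = panel, thresholds = thresholds,
                 category_levels = category_levels,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis workflow
#'
#' Reads the count table and auxiliary lists, then per genotype:
#' filters contaminants, runs the enrichment analysis, writes the hit
#' table, and writes one Venn partition per threshold. If an annotation
#' table is supplied, writes category summaries (with ANOVA when
#' several genotypes are present) and synaptic node lists; if a panel
#' list is supplied, writes the panel report. Every output is listed in
#' a manifest with MD5 checksums, and a JSON-lines run log records the
#' seed, filter counts and imputation counts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `results` (per-genotype enrichment
#'   results), `venns`, `summaries`, `manifest` and the output paths.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_event <- function(...) {
    writeLines(jsonlite::toJSON(list(...), auto_unbox = TRUE), log_con)
  }
  log_event(event = "start", seed = config$seed,
            version = as.character(utils::packageVersion("ibioid")))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  table <- stage("read_counts", read_count_table(config$counts))
  empty_list <- function(name) {
    structure(list(name = name, symbols = character(0)),
              class = "gene_list")
  }
  mito <- if (!is.null(config$mito)) {
    stage("read_mito", read_gene_list(config$mito, "mitochondrial"))
  } else empty_list("mitochondrial")
  contaminants <- if (!is.null(config$contaminants)) {
    stage("read_contaminants",
          read_gene_list(config$contaminants, "contaminants"))
  } else empty_list("contaminants")
  ann <- if (!is.null(config$annotation)) {
    stage("read_annotation", read_annotation_table(config$annotation))
  } else NULL
  panel <- if (!is.null(config$panel)) {
    stage("read_panel", read_gene_list(config$panel, "panel"))
  } else NULL

  genotypes <- unique(table$genotype)
  results <- list(); venns <- list(); paths <- character(0)

  for (g in genotypes) {
    sub <- count_table(table[table$genotype == g, ],
                       require_reference = FALSE)
    filt <- stage(paste0("filter_", g),
                  filter_contaminants(sub, mito, contaminants))
    flog <- attr(filt, "filter_log")
    log_event(event = "filter", genotype = g,
              n_removed_records = sum(flog$n_records),
              n_removed_symbols = nrow(flog))
    res <- stage(paste0("enrich_", g),
                 run_enrichment(filt, thresholds = config$thresholds))
    log_event(event = "enrichment", genotype = g,
              n_proteins = length(unique(res$protein_id)),
              n_imputed = attr(res, "provenance")$n_imputed_session_means)
    results[[g]] <- res
    p <- file.path(config$out_dir, paste0("hits_", tolower(g), ".tsv"))
    write_results(res, p); paths <- c(paths, p)

    venns[[g]] <- list()
    for (t in config$thresholds) {
      vp <- venn_partition(call_hits(res, t), res)
      venns[[g]][[format(t)]] <- vp
      p <- file.path(config$out_dir,
                     sprintf("venn_%s_%s.json", tolower(g), format(t)))
      write_results(vp, p); paths <- c(paths, p)
    }
  }

  summaries <- list()
  if (!is.null(ann)) {
    for (lv in config$category_levels) {
      cs <- stage(paste0("categories_", lv),
                  category_mean_log2fc(results, ann, lv))
      summaries[[lv]] <- cs
      p <- file.path(config$out_dir,
                     paste0("categories_",
                            gsub("[^a-z0-9]+", "_", lv), ".tsv"))
      write_results(cs, p); paths <- c(paths, p)
    }
    for (g in genotypes) {
      hits <- call_hits(results[[g]], 2.0)$union
      p <- file.path(config$out_dir,
                     paste0("nodes_", tolower(g), ".txt"))
      network_node_set(hits, ann, path = p); paths <- c(paths, p)
    }
  }
  if (!is.null(panel)) {
    pr <- stage("panel", panel_report(results, panel))
    p <- file.path(config$out_dir, "panel_report.tsv")
    readr::write_tsv(pr, p, progress = FALSE); paths <- c(paths, p)
  }

  manifest <- tibble::tibble(file = basename(paths),
                             md5 = unname(tools::md5sum(paths)))
  readr::write_tsv(manifest,
                   file.path(config$out_dir, "manifest.tsv"),
                   progress = FALSE)
  log_event(event = "done", n_outputs = length(paths))
  invisible(list(results = results, venns = venns,
                 summaries = summaries, manifest = manifest,
                 out_dir = config$out_dir))
}

#' Write a small self-contained fixture suite
#'
#' Generates toy input files sufficient to exercise the whole workflow:
#' a count table constructed so that exactly three planted proteins
#' exceed the 2.0-fold threshold, removal lists, an annotation table
#' and a panel list. Byte-identical for a given seed (the seed only
#' permutes the row order of the count table, which the reader must
#' undo).
#'
#' @param out_dir Directory to write into (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- c("AZ0001", "AZ0002", "AZ0003",  # planted hits (FC 4)
                "BGA", "BGB", "BGC",           # background (FC 1)
                "MITO0001", "PC")              # removed by lists
  base <- c(3, 3, 3, 8, 8, 8, 10, 12)
  bait_mult <- c(4, 4, 4, 1, 1, 1, 1, 1)
  rows <- list()
  for (s in 1:2) for (r in 1:2) for (b in ALL_CONDITIONS) {
    mult <- if (b == REFERENCE) 1 else bait_mult
    rows[[length(rows) + 1]] <- tibble::tibble(
      protein_id = proteins, gene_symbol = proteins, bait = b,
      genotype = "CONTROL", session = s,
      replicate = (s - 1L) * 2L + r,
      peptide_count = as.integer(base * mult))
  }
  counts <- dplyr::bind_rows(rows)
  counts <- withr::with_seed(as.integer(seed),
                             counts[sample(nrow(counts)), ])
  paths <- c(
    counts = file.path(out_dir, "toy_counts.tsv"),
    mito = file.path(out_dir, "toy_mito.txt"),
    contaminants = file.path(out_dir, "toy_contaminants.txt"),
    annotation = file.path(out_dir, "toy_annotation.tsv"),
    panel = file.path(out_dir, "toy_panel.txt"))
  readr::write_tsv(counts, paths["counts"], progress = FALSE)
  writeLines("MITO0001", paths["mito"])
  writeLines(c("PC", "PCCA"), paths["contaminants"])
  readr::write_tsv(tibble::tibble(
    gene_symbol = c("AZ0001", "AZ0002", "BGA"),
    path = c("synapse/presynapse/active zone",
             "synapse/presynapse", "synapse/postsynapse")),
    paths["annotation"], progress = FALSE)
  writeLines(c("AZ0001", "BGA"), paths["panel"])
  invisible(paths)
}
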