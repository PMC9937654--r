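#' Construct and validate a peptide-count table
#'
#' The central data structure of the pipeline: a long-format table of
#' spectral (peptide) counts keyed by protein, bait condition, genotype,
#' mass-spectrometry session and repeat. A protein absent from a
#' (bait, session) block is interpreted downstream as count 0 in every
#' repeat of that block; mass-spec output omits undetected proteins, so
#' absence is not recorded explicitly.
#'
#' @param df A data frame with columns `protein_id`, `gene_symbol`,
#'   `bait`, `genotype`, `session`, `replicate`, `peptide_count`.
#' @param require_reference If `TRUE` (default), every (genotype, session)
#'   block must contain the `TDTOMATO` reference condition.
#'
#' @return A tibble of class `count_table` with normalized gene symbols.
#' @export
count_table <- function(df, require_reference = TRUE) {
  required <- c("protein_id", "gene_symbol", "bait", "genotype",
                "session", "replicate", "peptide_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("count table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[required]

  cnt <- df$peptide_count
  if (!is.numeric(cnt)) {
    stop("peptide_count must be numeric", call. = FALSE)
  }
  bad <- which(!is.finite(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad) > 0) {
    stop("peptide_count must be a non-negative integer; offending row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$peptide_count <- as.integer(round(cnt))

  df$gene_symbol <- normalize_gene_symbol(df$gene_symbol)
  df$bait <- toupper(trimws(as.character(df$bait)))
  df$genotype <- toupper(trimws(as.character(df$genotype)))
  df$session <- as.integer(df$session)
  df$replicate <- as.integer(df$replicate)

  bad_bait <- setdiff(unique(df$bait), ALL_CONDITIONS)
  if (length(bad_bait) > 0) {
    stop("unknown bait condition(s): ", paste(bad_bait, collapse = ", "),
         "; expected one of ", paste(ALL_CONDITIONS, collapse = ", "),
         call. = FALSE)
  }
  bad_gt <- setdiff(unique(df$genotype), GENOTYPES)
  if (length(bad_gt) > 0) {
    stop("unknown genotype(s): ", paste(bad_gt, collapse = ", "),
         "; expected one of ", paste(GENOTYPES, collapse = ", "),
         call. = FALSE)
  }

  key <- paste(df$protein_id, df$bait, df$genotype, df$session,
               df$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicated (protein, bait, genotype, session, replicate) key; ",
         "offending row(s): ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }

  if (require_reference) {
    blocks <- unique(df[c("genotype", "session")])
    for (i in seq_len(nrow(blocks))) {
      sub <- df$bait[df$genotype == blocks$genotype[i] &
                     df$session == blocks$session[i]]
      if (!REFERENCE %in% sub) {
        stop("reference condition ", REFERENCE,
             " missing from genotype ", blocks$genotype[i],
             ", session ", blocks$session[i], call. = FALSE)
      }
    }
  }

  # canonical row order makes ingestion order-invariant
  df <- df[order(df$genotype, df$protein_id, df$bait, df$session,
                 df$replicate), ]
  class(df) <- c("count_table", class(tibble::tibble()))
  df
}

#' Normalize gene symbols
#'
#' Symbols are matched across species databases and curated lists by a
#' single declared rule: strip surrounding whitespace and uppercase. An
#' optional synonym map (named character vector, `names` = alias,
#' values = preferred symbol, both compared after normalization) is
#' applied afterwards, before any list-membership test.
#'
#' @param x Character vector of gene symbols.
#' @param synonyms Optional named character vector mapping aliases to
#'   preferred symbols.
#' @return Character vector of normalized symbols.
#' @export
normalize_gene_symbol <- function(x, synonyms = NULL) {
  out <- toupper(trimws(as.character(x)))
  if (!is.null(synonyms)) {
    map <- setNames(toupper(trimws(as.character(synonyms))),
                    toupper(trimws(names(synonyms))))
    hit <- out %in% names(map)
    out[hit] <- unname(map[out[hit]])
  }
  out
}

#' Read a peptide-count table from delimited text
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named character vector mapping the canonical column
#'   names (`protein_id`, `gene_symbol`, `bait`, `genotype`, `session`,
#'   `replicate`, `peptide_count`) to the column names used in the file.
#'   Defaults to the identity mapping; a file column named `repeat` is
#'   accepted for `replicate` without configuration.
#' @param delim Field delimiter; tab by default, use `","` for CSV.
#' @inheritParams count_table
#'
#' @return A validated [count_table()].
#' @export
read_count_table <- function(path, schema = NULL, delim = "\t",
                             require_reference = TRUE) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  canonical <- c("protein_id", "gene_symbol", "bait", "genotype",
                 "session", "replicate", "peptide_count")
  mapping <- setNames(canonical, canonical)
  if ("repeat" %in% names(df) && !"replicate" %in% names(df)) {
    mapping["replicate"] <- "repeat"
  }
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), canonical)
    if (length(unknown) > 0) {
      stop("schema maps unknown field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mapping[names(schema)] <- unname(schema)
  }
  missing <- mapping[!mapping %in% names(df)]
  if (length(missing) > 0) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[unname(mapping)]
  names(df) <- names(mapping)
  count_table(df, require_reference = require_reference)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and lines starting with `#` are ignored; symbols are
#' normalized with [normalize_gene_symbol()]. Used for removal lists
#' (MitoCarta mitochondrial genes; purification contaminants such as
#' PC, PCCA, neutravidin and IgGs) and curated panels.
#'
#' @param path Path to a plain-text file.
#' @param name Short name for the list (e.g. `"mitocarta"`).
#' @param synonyms Optional synonym map, see [normalize_gene_symbol()].
#'
#' @return A `gene_list` object: a list with `name` and a character
#'   vector `symbols` (unique, sorted).
#' @export
read_gene_list <- function(path, name, synonyms = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_list(name, lines, synonyms = synonyms)
}

#' @rdname read_gene_list
#' @param symbols Character vector of gene symbols.
#' @export
gene_list <- function(name, symbols, synonyms = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  symbols <- normalize_gene_symbol(symbols, synonyms = synonyms)
  symbols <- sort(unique(symbols[nzchar(symbols)]))
  if (length(symbols) == 0) {
    warning("gene list '", name, "' is empty", call. = FALSE)
  }
  structure(list(name = name, symbols = symbols), class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat("<gene_list>", x$name, "-", length(x$symbols), "symbols\n")
  invisible(x)
}

#' Read a hierarchical annotation table
#'
#' Expects a two-column delimited file mapping gene symbols to
#' slash-delimited cellular-component category paths (one path per row,
#' e.g. `synapse/presynapse/active zone`), as exported from an ontology
#' such as SynGO. A gene may carry several non-mutually-exclusive paths;
#' a gene annotated to a child path counts at every ancestor level.
#'
#' @param path Path to the file; columns `gene_symbol` and `path`.
#' @param delim Field delimiter, tab by default.
#' @param synonyms Optional synonym map, see [normalize_gene_symbol()].
#'
#' @return An `annotation_table`: a tibble with columns `gene_symbol`
#'   and `path`.
#' @export
read_annotation_table <- function(path, delim = "\t", synonyms = NULL) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!all(c("gene_symbol", "path") %in% names(df))) {
    stop("annotation table needs columns gene_symbol and path",
         call. = FALSE)
  }
  annotation_table(df, synonyms = synonyms)
}

#' @rdname read_annotation_table
#' @param df Data frame with columns `gene_symbol`, `path`.
#' @export
annotation_table <- function(df, synonyms = NULL) {
  df <- tibble::as_tibble(df)[c("gene_symbol", "path")]
  df$gene_symbol <- normalize_gene_symbol(df$gene_symbol,
                                          synonyms = synonyms)
  df$path <- normalize_category_path(df$path)
  df <- dplyr::distinct(df)
  class(df) <- c("annotation_table", class(tibble::tibble()))
  df
}

normalize_category_path <- function(path) {
  parts <- strsplit(as.character(path), "/", fixed = TRUE)
  vapply(parts, function(p) paste(tolower(trimws(p)), collapse = "/"),
         character(1))
}

#' Genes annotated at or below a category level
#'
#' @param ann An [annotation_table()].
#' @param level Slash-delimited category path prefix
#'   (e.g. `"synapse/presynapse"`).
#' @return Character vector of gene symbols.
#' @export
annotated_genes <- function(ann, level) {
  level <- normalize_category_path(level)
  known <- unique(unlist(lapply(strsplit(ann$path, "/", fixed = TRUE),
                                function(p) {
                                  vapply(seq_along(p), function(k) {
                                    paste(p[seq_len(k)], collapse = "/")
                                  }, character(1))
                                })))
  if (!level %in% known) {
    stop("unknown category level '", level, "'; known levels: ",
         paste(sort(known), collapse = ", "), call. = FALSE)
  }
  hit <- ann$path == level | startsWith(ann$path, paste0(level, "/"))
  sort(unique(ann$gene_symbol[hit]))
}
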