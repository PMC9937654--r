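#' Exclusive three-bait overlap partition
#'
#' Partitions the union hit set into the seven exclusive regions of a
#' three-set Venn diagram, and records for every hit protein the
#' maximum final fold change over the baits in which it is a hit
#' together with the bait attaining it (the quantity that sets circle
#' size in Venn exports; area scales linearly with it). Bait-encoding
#' genes are flagged, not removed: they are displayed separately in
#' figures but remain members of their regions.
#'
#' @param hits A [call_hits()] result (single genotype and threshold).
#' @param result The [run_enrichment()] result the hits came from.
#'
#' @return A list of class `venn_partition`: `regions` (named list of
#'   protein-id vectors keyed e.g. `"RIM_PPCP"`,
#'   `"RIM_PPCP+ELKS2B"`, `"RIM_PPCP+ELKS2B+CAVB4"`), `counts`
#'   (named integer vector), `max_fc` (tibble: protein_id, max_fc,
#'   argmax_bait, is_bait_gene), `n_union`, `n_multi` (hits in >= 2
#'   baits), `n_all_three`, and `threshold`.
#' @export
venn_partition <- function(hits, result) {
  stopifnot(inherits(result, "enrichment_result"))
  sets <- hits$per_bait[BAITS]
  union <- sort(unique(unlist(sets)))
  membership <- vapply(BAITS, function(b) union %in% sets[[b]],
                       logical(length(union)))
  if (length(union) == 1) membership <- matrix(membership, nrow = 1)
  region_of <- apply(membership, 1, function(m) {
    paste(BAITS[m], collapse = "+")
  })
  region_names <- unlist(lapply(seq_along(BAITS), function(k) {
    combn(BAITS, k, paste, collapse = "+")
  }))
  regions <- lapply(region_names, function(r) union[region_of == r])
  names(regions) <- region_names

  n_baits <- rowSums(membership)
  if (length(union) == 0) {
    return(structure(list(
      regions = regions,
      counts = vapply(regions, length, integer(1)),
      max_fc = tibble::tibble(protein_id = character(),
                              max_fc = numeric(),
                              argmax_bait = character(),
                              is_bait_gene = logical()),
      n_union = 0L, n_multi = 0L, n_all_three = 0L,
      threshold = hits$threshold), class = "venn_partition"))
  }
  sub <- result[result$protein_id %in% union, ]
  sub <- sub[paste(sub$protein_id, sub$bait) %in%
               unlist(lapply(BAITS, function(b) {
                 paste(sets[[b]], b)
               })), ]
  max_fc <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sub), .data$protein_id),
    max_fc = max(.data$mean_fc),
    argmax_bait = .data$bait[which.max(.data$mean_fc)],
    .groups = "drop")
  max_fc$is_bait_gene <- max_fc$protein_id %in%
    result$protein_id[result$gene_symbol %in% BAIT_GENES]

  structure(list(
    regions = regions,
    counts = vapply(regions, length, integer(1)),
    max_fc = max_fc,
    n_union = length(union),
    n_multi = sum(n_baits >= 2),
    n_all_three = sum(n_baits == 3),
    threshold = hits$threshold
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> threshold", x$threshold, "-",
      x$n_union, "hits;", x$n_multi, "in >=2 baits;",
      x$n_all_three, "in all three\n")
  print(x$counts)
  invisible(x)
}

#' Annotated subset of a hit set
#'
#' Intersects a hit set with the genes annotated at or below an
#' ontology category level. Bait-encoding genes are excluded before
#' the fraction is computed, matching how annotation coverage of the
#' hit list is reported.
#'
#' @param hits Character vector of protein ids (gene symbols).
#' @param ann An [annotation_table()].
#' @param level Category path prefix, e.g. `"synapse"` or
#'   `"synapse/presynapse"`.
#' @param exclude_bait_genes Drop bait-encoding genes before computing
#'   the fraction (default `TRUE`).
#'
#' @return List: `annotated` (sorted subset), `n`, `n_hits` (after any
#'   bait-gene exclusion), `fraction`.
#' @export
annotate_hits <- function(hits, ann, level, exclude_bait_genes = TRUE) {
  genes <- annotated_genes(ann, level)
  hits <- unique(normalize_gene_symbol(hits))
  if (exclude_bait_genes) {
    hits <- setdiff(hits, unname(BAIT_GENES))
  }
  annotated <- sort(intersect(hits, genes))
  list(annotated = annotated,
       n = length(annotated),
       n_hits = length(hits),
       fraction = if (length(hits) > 0) length(annotated) / length(hits)
                  else NA_real_)
}

#' Fraction of a control hit set retained in a mutant
#'
#' @param control_hits,mutant_hits Protein-id vectors called at the
#'   same threshold.
#' @return `|control ∩ mutant| / |control|`.
#' @export
overlap_fraction <- function(control_hits, mutant_hits) {
  control_hits <- unique(control_hits)
  if (length(control_hits) == 0) {
    stop("control hit set is empty", call. = FALSE)
  }
  length(intersect(control_hits, mutant_hits)) / length(control_hits)
}

#' Size and share of a single-bait-only Venn region
#'
#' @param partition A [venn_partition()].
#' @param bait One of the bait condition names.
#' @return List: `count` (proteins hit in this bait only) and
#'   `fraction` of the union hit set (0 if the union is empty).
#' @export
single_bait_fraction <- function(partition, bait) {
  stopifnot(inherits(partition, "venn_partition"))
  bait <- match.arg(toupper(bait), BAITS)
  count <- length(partition$regions[[bait]])
  list(count = count,
       fraction = if (partition$n_union > 0) count / partition$n_union
                  else 0)
}

#' Node list for external network analysis
#'
#' Selects the hit proteins carrying a synaptic ontology annotation and
#' returns them as a symbol list suitable for pasting into the STRING
#' web interface (edge retrieval and cluster labeling happen there, not
#' in this package).
#'
#' @param hits Character vector of hit protein ids.
#' @param ann An [annotation_table()].
#' @param level Category level defining "synaptic" (default
#'   `"synapse"`).
#' @param exclude_bait_genes Drop bait-encoding genes (default `TRUE`,
#'   matching the annotated-hit selection).
#' @param path Optional file to write the list to, one symbol per line.
#'
#' @return Character vector of node symbols (invisibly if written).
#' @export
network_node_set <- function(hits, ann, level = "synapse",
                             exclude_bait_genes = TRUE, path = NULL) {
  nodes <- annotate_hits(hits, ann, level,
                         exclude_bait_genes = exclude_bait_genes)$annotated
  if (!is.null(path)) {
    writeLines(nodes, path)
    return(invisible(nodes))
  }
  nodes
}
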