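#' Configuration for the synthetic peptide-count generator
#'
#' Builds a validated configuration for [simulate_dataset()] /
#' [simulate_genotype_panel()]. The generator emulates the statistical
#' structure of a multi-bait proximity-labeling experiment: four
#' conditions (three release-site baits plus the soluble-axon reference),
#' repeats grouped into mass-spectrometry sessions, overdispersed
#' spectral counts, a planted release-site protein subset enriched in
#' bait conditions, bait self-biotinylation spikes, mitochondrial and
#' purification-contaminant background, detection dropout, and genotype
#' effects on release-site enrichment.
#'
#' Count law: negative binomial (Gamma-Poisson) with a single global
#' overdispersion parameter, `Var = mu + dispersion * mu^2`. Per-protein
#' baseline abundances are log-normal. Dropout is modeled as independent
#' post-hoc zeroing of records, which exercises the 0.5-imputation branch
#' of the enrichment pipeline by construction.
#'
#' @param n_proteins Number of proteins in the universe (>= 10).
#' @param frac_release_site Fraction of proteins planted as release-site
#'   components (enriched in every bait condition).
#' @param frac_mito Fraction flagged mitochondrial (background abundance;
#'   removable via the MitoCarta-style list from [sim_gene_lists()]).
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and SD of the
#'   per-protein baseline abundance (log-normal).
#' @param dispersion Negative-binomial overdispersion (> 0).
#' @param enrichment_factor Multiplier (>= 1) applied to release-site
#'   proteins in bait conditions.
#' @param self_bait_factor Multiplier (>= 1) applied to each bait's own
#'   gene in its own condition only (self-biotinylation spike).
#' @param dropout_prob Probability that any single (protein, condition,
#'   repeat) record is zeroed (detection failure).
#' @param genotype_effect Named list: genotype -> named numeric vector of
#'   per-bait multipliers in `[0, 1]` applied to `enrichment_factor`.
#'   `CONTROL` must map every bait to 1.
#' @param n_sessions Number of mass-spectrometry sessions (1 or 2).
#' @param repeats_per_session Repeats acquired within each session.
#' @param session_effect_sd SD of an optional multiplicative log-normal
#'   session factor (0 = off). Session-wise fold-change normalization
#'   should cancel it.
#' @param seed Integer seed; identical config + seed gives an identical
#'   dataset.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1200,
                       frac_release_site = 0.05,
                       frac_mito = 0.15,
                       baseline_log_mean = log(24),
                       baseline_log_sd = 0.4,
                       dispersion = 0.01,
                       enrichment_factor = 8,
                       self_bait_factor = 20,
                       dropout_prob = 0.005,
                       genotype_effect = default_genotype_effect(),
                       n_sessions = 2,
                       repeats_per_session = 2,
                       session_effect_sd = 0,
                       seed = 1L) {
  cfg <- list(n_proteins = n_proteins,
              frac_release_site = frac_release_site,
              frac_mito = frac_mito,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion = dispersion,
              enrichment_factor = enrichment_factor,
              self_bait_factor = self_bait_factor,
              dropout_prob = dropout_prob,
              genotype_effect = genotype_effect,
              n_sessions = as.integer(n_sessions),
              repeats_per_session = as.integer(repeats_per_session),
              session_effect_sd = session_effect_sd,
              seed = as.integer(seed))

  check_num <- function(field, lo, hi = Inf) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        v < lo || v > hi) {
      stop("invalid sim_config field '", field, "'", call. = FALSE)
    }
  }
  check_num("n_proteins", 10)
  check_num("frac_release_site", 0, 1)
  check_num("frac_mito", 0, 1)
  check_num("baseline_log_sd", 1e-8)
  check_num("dispersion", 1e-8)
  check_num("enrichment_factor", 1)
  check_num("self_bait_factor", 1)
  check_num("dropout_prob", 0, 1)
  check_num("n_sessions", 1, 2)
  check_num("repeats_per_session", 1)
  check_num("session_effect_sd", 0)
  if (cfg$frac_release_site + cfg$frac_mito > 1) {
    stop("invalid sim_config field 'frac_release_site': ",
         "frac_release_site + frac_mito exceeds 1", call. = FALSE)
  }
  ge <- cfg$genotype_effect
  if (!is.list(ge) || !all(GENOTYPES %in% names(ge))) {
    stop("invalid sim_config field 'genotype_effect': must name every ",
         "genotype (", paste(GENOTYPES, collapse = ", "), ")",
         call. = FALSE)
  }
  for (g in names(ge)) {
    v <- ge[[g]]
    if (!is.numeric(v) || !all(BAITS %in% names(v)) ||
        any(v[BAITS] < 0 | v[BAITS] > 1)) {
      stop("invalid sim_config field 'genotype_effect': per-bait ",
           "multipliers for ", g, " must lie in [0, 1] and name every bait",
           call. = FALSE)
    }
  }
  if (any(ge$CONTROL[BAITS] != 1)) {
    stop("invalid sim_config field 'genotype_effect': CONTROL ",
         "multipliers must all be 1", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_genotype_effect <- function() {
  list(CONTROL  = c(RIM_PPCP = 1,   ELKS2B = 1,   CAVB4 = 1),
       RIM_CKO  = c(RIM_PPCP = 0.2, ELKS2B = 0.05, CAVB4 = 0.05),
       SYT1_CKO = c(RIM_PPCP = 1,   ELKS2B = 1,   CAVB4 = 1))
}

# Bait-encoding genes: each is planted as a release-site protein and
# receives the self-biotinylation spike in its own condition.
BAIT_GENES <- c(RIM_PPCP = "RIMS1", ELKS2B = "ERC2", CAVB4 = "CACNB4")
CONTAMINANT_GENES <- c("PC", "PCCA")

# The protein universe (symbols, flags, baseline means) is shared across
# genotypes of the same config; only the counts are redrawn.
sim_universe <- function(config) {
  n <- config$n_proteins
  n_rs <- max(round(config$frac_release_site * n), length(BAIT_GENES))
  n_mito <- round(config$frac_mito * n)
  n_cont <- length(CONTAMINANT_GENES)
  n_bg <- n - n_rs - n_mito - n_cont
  if (n_bg < 0) {
    stop("invalid sim_config field 'n_proteins': too small for the ",
         "requested fractions", call. = FALSE)
  }
  symbols <- c(unname(BAIT_GENES),
               sprintf("RS%04d", seq_len(n_rs - length(BAIT_GENES))),
               sprintf("MITO%04d", seq_len(n_mito)),
               CONTAMINANT_GENES,
               sprintf("BG%04d", seq_len(n_bg)))
  withr::with_seed(config$seed, {
    baseline <- rlnorm(n, meanlog = config$baseline_log_mean,
                       sdlog = config$baseline_log_sd)
  })
  tibble::tibble(
    protein_id = symbols,
    gene_symbol = symbols,
    is_release_site = c(rep(TRUE, n_rs), rep(FALSE, n - n_rs)),
    is_mito = c(rep(FALSE, n_rs), rep(TRUE, n_mito),
                rep(FALSE, n_cont + n_bg)),
    is_contaminant = c(rep(FALSE, n_rs + n_mito), rep(TRUE, n_cont),
                       rep(FALSE, n_bg)),
    baseline_mean = baseline
  )
}

#' Simulate a peptide-count dataset with ground truth
#'
#' Draws negative-binomial counts with mean
#' `baseline_mean * effective_enrichment(bait) * session factor`,
#' applies detection dropout, and returns the long-format count table
#' together with the planted truth. Rows with count 0 are omitted from
#' the table, as in real mass-spec output; downstream code treats
#' absence as zero.
#'
#' @param config A [sim_config()].
#' @param genotype Genotype to simulate (default `"CONTROL"`).
#' @param n_sessions,repeats_per_session Optional overrides of the
#'   config values (used by [simulate_genotype_panel()], where mutants
#'   are measured in a single session).
#'
#' @return A list with elements `counts` (a [count_table()]) and `truth`
#'   (a tibble with per-protein flags, baseline means, and effective
#'   per-bait enrichment; the reference condition always has effective
#'   enrichment 1).
#' @export
simulate_dataset <- function(config, genotype = "CONTROL",
                             n_sessions = config$n_sessions,
                             repeats_per_session = config$repeats_per_session) {
  stopifnot(inherits(config, "sim_config"))
  genotype <- match.arg(toupper(genotype), GENOTYPES)
  if (!genotype %in% names(config$genotype_effect)) {
    stop("genotype_effect does not define genotype ", genotype,
         call. = FALSE)
  }
  uni <- sim_universe(config)
  n <- nrow(uni)

  mult <- config$genotype_effect[[genotype]]
  # effective enrichment per protein x condition
  eff <- matrix(1, nrow = n, ncol = length(ALL_CONDITIONS),
                dimnames = list(uni$gene_symbol, ALL_CONDITIONS))
  for (b in BAITS) {
    eff[uni$is_release_site, b] <- config$enrichment_factor * mult[[b]]
    eff[BAIT_GENES[[b]], b] <- config$self_bait_factor
  }

  truth <- uni
  for (b in BAITS) truth[[paste0("eff_", b)]] <- eff[, b]

  seed_offset <- (match(genotype, GENOTYPES) - 1L) * 1000003L + 17L
  counts <- withr::with_seed(config$seed + seed_offset, {
    out <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      s_factor <- if (config$session_effect_sd > 0) {
        rlnorm(1, 0, config$session_effect_sd)
      } else 1
      mu <- as.vector(outer(uni$baseline_mean, rep(1, length(ALL_CONDITIONS))) *
                        eff) * s_factor
      reps <- vector("list", repeats_per_session)
      for (r in seq_len(repeats_per_session)) {
        cnt <- rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
        if (config$dropout_prob > 0) {
          cnt[runif(length(cnt)) < config$dropout_prob] <- 0L
        }
        reps[[r]] <- tibble::tibble(
          protein_id = rep(uni$protein_id, times = length(ALL_CONDITIONS)),
          gene_symbol = rep(uni$gene_symbol, times = length(ALL_CONDITIONS)),
          bait = rep(ALL_CONDITIONS, each = n),
          genotype = genotype,
          session = s,
          replicate = (s - 1L) * repeats_per_session + r,
          peptide_count = cnt
        )
      }
      out[[s]] <- dplyr::bind_rows(reps)
    }
    dplyr::bind_rows(out)
  })
  counts <- counts[counts$peptide_count > 0, ]
  list(counts = count_table(counts), truth = truth)
}

#' Simulate a genotype panel sharing one protein universe
#'
#' Emulates the full study design: the control genotype is measured in
#' `config$n_sessions` sessions, while each conditional-knockout
#' genotype is measured in a single session (as mutant datasets were).
#' All genotypes share the same protein universe and baseline means.
#'
#' @param config A [sim_config()]; `genotype_effect` must define all
#'   three genotypes.
#' @param mutant_sessions Sessions for the knockout genotypes (default 1).
#'
#' @return Named list: genotype -> list(counts, truth).
#' @export
simulate_genotype_panel <- function(config, mutant_sessions = 1L) {
  stopifnot(inherits(config, "sim_config"))
  missing <- setdiff(GENOTYPES, names(config$genotype_effect))
  if (length(missing) > 0) {
    stop("genotype_effect does not define genotype(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(GENOTYPES, function(g) {
    ns <- if (g == "CONTROL") config$n_sessions else as.integer(mutant_sessions)
    simulate_dataset(config, genotype = g, n_sessions = ns)
  })
  names(out) <- GENOTYPES
  out
}

#' Removal lists matching a simulated dataset
#'
#' Builds the mitochondrial and contaminant [gene_list()]s implied by a
#' simulation truth table, playing the role of the MitoCarta export and
#' the PC/PCCA/neutravidin/IgG contaminant list for synthetic data.
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @return List with elements `mito` and `contaminants`.
#' @export
sim_gene_lists <- function(truth) {
  list(mito = gene_list("mitocarta_synthetic",
                        truth$gene_symbol[truth$is_mito]),
       contaminants = gene_list("contaminants_synthetic",
                                truth$gene_symbol[truth$is_contaminant]))
}
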