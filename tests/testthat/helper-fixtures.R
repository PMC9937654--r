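# Builders for small deterministic fixtures and independent oracles.

# A toy count table: `spec` is a named list protein -> list(bait -> counts
# matrix/vector). Counts are given per (session, replicate) as a vector
# ordered s1r1, s1r2, s2r3, s2r4 (2 sessions x 2 repeats) unless
# sessions/repeats are overridden.
toy_count_table <- function(spec, genotype = "CONTROL", n_sessions = 2,
                            reps = 2) {
  rows <- list()
  for (p in names(spec)) {
    for (b in names(spec[[p]])) {
      cnt <- spec[[p]][[b]]
      i <- 0
      for (s in seq_len(n_sessions)) for (r in seq_len(reps)) {
        i <- i + 1
        if (cnt[i] > 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            protein_id = p, gene_symbol = p, bait = b,
            genotype = genotype, session = s,
            replicate = (s - 1) * reps + r,
            peptide_count = cnt[i])
        }
      }
    }
  }
  count_table(dplyr::bind_rows(rows), require_reference = FALSE)
}

toy_annotation <- function() {
  annotation_table(tibble::tibble(
    gene_symbol = c("P1", "P2", "P4", "P4"),
    path = c("synapse/presynapse", "synapse/postsynapse",
             "synapse/presynapse/active zone", "synapse/postsynapse")))
}

# Independent classical sums-of-squares oracle for a balanced two-way
# factorial design with interaction (explicit marginal-mean arithmetic;
# no model fitting).
anova_balanced_oracle <- function(df) {
  a <- factor(df$genotype); b <- factor(df$bait); y <- df$value
  grand <- mean(y)
  na <- nlevels(a); nb <- nlevels(b)
  r <- nrow(df) / (na * nb)
  ss_a <- 0
  for (ai in levels(a)) ss_a <- ss_a + sum(a == ai) * (mean(y[a == ai]) - grand)^2
  ss_b <- 0
  for (bi in levels(b)) ss_b <- ss_b + sum(b == bi) * (mean(y[b == bi]) - grand)^2
  ss_cells <- 0
  ss_e <- 0
  for (ai in levels(a)) for (bi in levels(b)) {
    cell <- y[a == ai & b == bi]
    ss_cells <- ss_cells + length(cell) * (mean(cell) - grand)^2
    ss_e <- ss_e + sum((cell - mean(cell))^2)
  }
  ss_ab <- ss_cells - ss_a - ss_b
  df_a <- na - 1; df_b <- nb - 1; df_ab <- df_a * df_b
  df_e <- na * nb * (r - 1)
  list(F_genotype = (ss_a / df_a) / (ss_e / df_e),
       F_bait = (ss_b / df_b) / (ss_e / df_e),
       F_interaction = (ss_ab / df_ab) / (ss_e / df_e))
}

# Exhaustive Otsu oracle: for every candidate cut between histogram bins,
# compute the weighted within-class variance of the bin mids by explicit
# loops and return the cut minimizing it (lowest bin on ties).
otsu_exhaustive_oracle <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best_k <- NA_integer_
  best_wcv <- Inf
  for (k in 1:(n_bins - 1)) {
    idx0 <- 1:k; idx1 <- (k + 1):n_bins
    w0 <- sum(counts[idx0]); w1 <- sum(counts[idx1])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[idx0] * mids[idx0]) / w0
    mu1 <- sum(counts[idx1] * mids[idx1]) / w1
    v0 <- sum(counts[idx0] * (mids[idx0] - mu0)^2)
    v1 <- sum(counts[idx1] * (mids[idx1] - mu1)^2)
    wcv <- v0 + v1
    if (wcv < best_wcv - 1e-12) {
      best_wcv <- wcv
      best_k <- k
    }
  }
  breaks[best_k + 1]
}

# Pipeline shorthand: simulate -> filter -> enrich -> union hits.
sim_hits <- function(cfg, genotype = "CONTROL", threshold = 2.0, ...) {
  sim <- simulate_dataset(cfg, genotype = genotype, ...)
  gl <- sim_gene_lists(sim$truth)
  tab <- filter_contaminants(sim$counts, gl$mito, gl$contaminants)
  res <- run_enrichment(tab)
  list(sim = sim, res = res, hits = call_hits(res, threshold))
}

# Balanced two-way factorial dataset with an optional planted cell shift.
balanced_design <- function(na, nb, r, seed, delta = 0) {
  withr::with_seed(seed, {
    g <- rep(paste0("G", seq_len(na)), each = nb * r)
    b <- rep(rep(paste0("B", seq_len(nb)), each = r), na)
    y <- rnorm(na * nb * r)
    y[g == "G1" & b == "B1"] <- y[g == "G1" & b == "B1"] + delta
    tibble::tibble(value = y, genotype = g, bait = b)
  })
}

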