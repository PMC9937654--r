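---
title: "Fold-change enrichment analysis for multi-bait proximity proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold-change enrichment analysis for multi-bait proximity proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibioid)
```

## The analysis problem

In vivo biotin identification (iBioID) fuses a promiscuous biotin ligase
(BirA*) to a bait protein so that proteins within roughly 10–50 nm are
biotinylated, affinity-purified and identified by mass spectrometry.
When several release-site baits (here RIM^PPCP^, ELKS2β and Ca~V~β4) are
compared against a soluble axonal reference bait (BirA-tdTomato), the
ratio of spectral counts measures how concentrated each protein is near
release sites relative to the general axonal proteome.

`ibioid` implements that comparison as a tested pipeline:

1. **Filtering.** Mitochondrial proteins (a MitoCarta-style removal
   list) and purification contaminants (pyruvate carboxylase, PCCA,
   neutravidin, IgGs) are removed before enrichment analysis.
   Mitochondrial removal can be skipped (`keep_mito = TRUE`) for
   whole-proteome views and curated-panel reports, which conventionally
   retain them.
2. **Session averaging with pseudocount imputation.** Peptide counts
   are averaged over the repeats acquired in the same mass-spectrometry
   session. A session average of exactly zero is assigned 0.5 so that
   every ratio and logarithm is defined. The same floor applies to
   numerator and denominator: it is the only reading under which both
   the "zero session average" rule and the "zero in the denominator"
   rule are consistent. A protein absent from a (bait, session) block
   is count 0 in every repeat — mass-spec output omits undetected
   proteins, so absence is not data loss but a zero observation.
   A side effect of the 0.5 floor is an inclusion rule: a protein seen
   once with a single peptide has session mean 0.5, indistinguishable
   from undetected, so a single singleton detection carries no
   evidence.
3. **Fold change.** Per session, each bait's session average is divided
   by the reference session average; the per-session fold changes are
   then averaged *unweighted* across sessions (sessions are the unit of
   replication, not repeats). Single-session datasets — the knockout
   genotypes here — pass through unchanged. `log2_fc = log2(mean_fc)`,
   computed after averaging, in that order.
4. **Hit calling.** A protein is a hit for a bait when its final fold
   change is at least the threshold (inclusive; default 2.0, with 1.5
   and 2.5 as standard alternates). Inclusive thresholds make hit sets
   nested across thresholds, which the tests assert as an invariant.
5. **Downstream summaries.** Exclusive seven-region overlap (Venn)
   partitions with per-protein maximum enrichment (circle size),
   ontology-category means with two-way ANOVA, control-versus-mutant
   overlap fractions, curated gene-panel reports, and node lists for
   external network analysis.

Deliberately absent: per-protein significance testing. The method is a
pure fold-change threshold; the package does not add p-values the
design cannot support (two repeats per session).

## Data model and conventions

Counts live in a long-format `count_table` keyed by
(protein, bait, genotype, session, repeat), with four condition levels
(`RIM_PPCP`, `ELKS2B`, `CAVB4`, `TDTOMATO`) and three genotypes
(`CONTROL`, `RIM_CKO`, `SYT1_CKO`). Gene symbols are normalized by one
declared rule — trim whitespace, uppercase, then an optional synonym
map — applied identically to tables, removal lists, annotations and
panels, because bait cDNAs and curated lists routinely mix species
conventions and no finer mapping rule is defensible from the inputs.

Annotation tables map gene symbols to slash-delimited category paths
(`synapse/presynapse/active zone`). Paths are prefix-consistent: a gene
annotated to a child level counts at every ancestor level, and a gene
may carry several non-exclusive paths. Two reporting rules follow the
field's conventions: bait-encoding genes are excluded from annotation
fractions and node lists (they are displayed separately, not counted as
discoveries), and in category means the self-biotinylated bait gene is
dropped from *its own* bait condition only, since self-biotinylation
would otherwise inflate that cell.

## The synthetic-data generator

`simulate_dataset()` exists so that every downstream stage is testable
against planted ground truth without any external download. It emulates
the study design: four conditions, two sessions of two repeats for the
control genotype, single-session mutants, a planted release-site subset
(5% of proteins) enriched `enrichment_factor`-fold in all bait
conditions, a self-biotinylation spike (`self_bait_factor = 20`) for
each bait's own gene in its own condition, 15% mitochondrial and two
contaminant background proteins, per-record detection dropout, and
per-genotype multipliers on the planted enrichment.

Counts are negative binomial (Gamma–Poisson,
`Var = mu + dispersion * mu^2`) around log-normal per-protein baselines
— the standard minimal model for overdispersed spectral counts.
Dropout is post-hoc zeroing, independent per record, so the
0.5-imputation branch is exercised by construction. An optional
log-normal session factor models batch intensity shifts; session-wise
normalization cancels it, which a test asserts.

### Where the default parameter values come from

The defaults are frozen study conditions, chosen once from a
design-phase recovery experiment and not revisited:

| parameter | default | meaning |
|---|---|---|
| `n_proteins` | 1200 | detected-proteome size, matching the ~1200 proteins a reference condition detects |
| `frac_release_site` | 0.05 | planted release-site fraction |
| `frac_mito` | 0.15 | mitochondrial background, the fraction such experiments typically remove |
| `baseline_log_mean` | log(24) | median baseline spectral count 24 |
| `baseline_log_sd` | 0.4 | spread of baseline abundances |
| `dispersion` | 0.01 | weak overdispersion beyond Poisson |
| `enrichment_factor` | 8 | planted effect in bait conditions |
| `self_bait_factor` | 20 | self-biotinylation spike |
| `dropout_prob` | 0.005 | per-record detection failure |
| `genotype_effect` | RIM_CKO (0.2, 0.05, 0.05); SYT1_CKO (1, 1, 1) | multipliers on `enrichment_factor` per bait |

The abundance and noise values deserve honesty. A fold-change threshold
computed from two repeats per session has no replication-based error
control, so its false-discovery behavior is set entirely by the count
noise. A Monte-Carlo sweep during design showed that with sparse,
strongly overdispersed counts (log-normal spread ≈ 1, median < 10,
dispersion ≥ 0.1 — arguably closer to raw spectral-count reality) the
false-discovery proportion among 2.0-fold hits is 0.4–0.8: most hits
are noise from low-abundance proteins whose reference average collapses
to the 0.5 floor. The generator therefore emulates the cleaner,
moderate-abundance regime in which the planted-recovery property
(sensitivity ≥ 0.9, false-discovery proportion ≤ 0.1 at an 8-fold
planted effect) is achievable: median counts in the twenties, weak
overdispersion, rare dropout. At the frozen defaults, measured over
generator seeds 1–10 at n = 1000: sensitivity 1.000, false-discovery
proportion 0.050.

Consequently, passing tests certify the *pipeline arithmetic and its
set-level behavior*, not that a 2.0-fold cutoff controls error on real
sparse proteomics data — on such data it demonstrably does not, which
is worth knowing when interpreting any fold-change-thresholded hit
list. Real data also violate the generator in other ways it does not
pretend to capture: correlated dropout across repeats, composition
effects from the affinity purification, abundance-dependent dispersion,
and shared-peptide ambiguity in protein inference.

The knockout multipliers encode the biology being modeled: scaffold
knockout (RIM) collapses release-site enrichment for the two
non-restoring baits to below baseline (0.05 × 8 = 0.4, i.e. depletion)
while the RIM-derived bait partially restores scaffolding
(0.2 × 8 = 1.6, mostly sub-threshold); sensor knockout (Syt-1) leaves
enrichment untouched. At the defaults this reproduces the study's
qualitative structure in 10/10 design-phase seeds: knockout hit counts
well below control, the RIM-bait-only region dominating the knockout
Venn union (0.43–0.65 of hits), and single-session sensor-knockout hit
counts within 1.1–1.3× of control (slightly above, because one session
of two repeats averages less noise than two sessions — the band
[0.6, 1.5] is the frozen reading of "comparable").

## The synaptosome imaging module

The companion module re-implements the confocal synaptosome
quantification: per-channel Otsu thresholds, 8-connected component
labeling, inclusive physical size gates (0.2–1 µm² for TH, 0.15–2 µm²
for Bassoon and the target stain; pixel area = `pixel_size_um`², no
sub-pixel correction), classification of TH⁺ ROIs by Bassoon content,
and an unpaired two-tailed Student's t-test plus a two-sample
Kolmogorov–Smirnov test on per-ROI target intensities.

Numerical choices worth stating:

- **Otsu** maximizes between-class variance over a 256-bin histogram;
  ties break to the lowest qualifying bin, making the threshold
  deterministic. A constant image is a degenerate-input error, not a
  silent zero. The implementation is checked bin-for-bin against an
  exhaustive within-class-variance search in the tests.
- **Connectivity** is 8-connected by default and configurable to 4;
  the analysis is 2-D per image.
- **Classification** defaults to the overlap rule: a TH ROI is
  Bassoon-positive when it shares ≥ 1 pixel with a detected Bassoon
  ROI, Bassoon-negative when (non-overlapping and) its mean Bassoon
  signal is below 1× the image-mean Bassoon intensity, and otherwise
  excluded from both groups rather than forced into one. A symmetric
  intensity-cutoff rule (`rule = "intensity"`) is provided as an
  alternative; neither is claimed to be the historical procedure's
  exact definition, which is why both are exposed.
- **Pixel size is a required input**; the synthetic scenes state it
  explicitly (0.15 µm defaults) and real use must supply the
  calibrated value.

The image generator places Gaussian spots with a minimum separation,
co-locates Bassoon spots with a configurable fraction of TH particles,
shifts the mean target amplitude by `effect_size` for Bassoon-positive
particles, and adds Gaussian read noise. Under the null
(`effect_size = 0`) the groups are exchangeable, so the t-test should
reject at its nominal rate: over 500 generated images the measured
false-positive rate at α = 0.05 is 0.054, the end-to-end calibration
the acceptance suite re-checks.

## Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which the asserted properties are
stable: 500-protein datasets for the 50-dataset nesting/conservation
sweep; 1000 proteins × 10 seeds for planted recovery; the full default
configuration (1200 proteins) × 10 seeds for the genotype-panel
ordering; 100 random balanced designs (up to 4 × 3 × 10 observations)
for the ANOVA oracle; 100 random 24 × 24 images for the Otsu oracle;
and 500 simulated images for imaging null calibration. The whole suite
runs in about a minute on one CPU.

## Known limitations

- The enrichment statistic is the study's: no per-protein inference,
  no multiplicity control over hits, no shrinkage of low-count ratios.
- Session structure is taken from the data (`session`, `repeat`
  columns); the pipeline does not attempt batch inference.
- The annotation-dependent counts depend entirely on the supplied
  annotation export and release; the package treats the table as data.
- Network analysis stops at node-list export; edge retrieval and
  cluster labeling belong to the external STRING service.
- The imaging module is per-image 2-D ROI analysis; z-stacks,
  deconvolution and sub-pixel colocalization are out of scope.
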