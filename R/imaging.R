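#' Multichannel synaptosome image container
#'
#' @param channels Named list of numeric matrices of identical shape;
#'   conventional channel names are `TH` (dopamine-axon marker),
#'   `BASSOON` (release-site marker) and `TARGET` (the stained protein
#'   under test).
#' @param pixel_size_um Physical pixel edge length in micrometers; must
#'   be supplied, it is never inferred.
#'
#' @return A list of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size_um) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all channels must have identical shape", call. = FALSE)
  }
  for (ch in channels) {
    if (!is.matrix(ch) || !all(is.finite(ch)) || any(ch < 0)) {
      stop("channel intensities must be finite, non-negative matrices",
           call. = FALSE)
    }
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive number", call. = FALSE)
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "multichannel_image")
}

#' Read a multichannel image from single-plane TIFF files
#'
#' @param paths Named character vector: channel name -> TIFF path (one
#'   single-plane grayscale image per file).
#' @param pixel_size_um Pixel edge length in micrometers.
#' @return A [multichannel_image()].
#' @export
read_multichannel_tiff <- function(paths, pixel_size_um) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF files requires the 'tiff' package", call. = FALSE)
  }
  channels <- lapply(paths, function(p) {
    img <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(img)) == 3) img <- img[, , 1]
    as.matrix(img)
  })
  names(channels) <- names(paths)
  multichannel_image(channels, pixel_size_um)
}

#' Otsu intensity threshold
#'
#' Histogram-based binarization threshold maximizing the between-class
#' intensity variance; ties are broken by the lowest qualifying bin.
#' Pixels strictly above the returned value are foreground.
#'
#' @param channel Numeric matrix (or vector) of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return Scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(channel, n_bins = 256) {
  x <- as.numeric(channel)
  if (!all(is.finite(x))) stop("intensities must be finite", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (lo == hi) {
    stop("degenerate input: constant image has no Otsu threshold",
         call. = FALSE)
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w <- cumsum(counts)
  total <- w[n_bins]
  csum <- cumsum(counts * mids)
  gsum <- csum[n_bins]
  # candidate k: background = bins 1..k, foreground = bins (k+1)..n_bins
  k <- seq_len(n_bins - 1)
  w0 <- w[k]; w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- csum[k] / w0
  mu1 <- (gsum - csum[k]) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  best <- which.max(bcv)   # which.max takes the first (lowest) maximum
  breaks[best + 1]
}

#' Label connected components of a binary mask
#'
#' Two-pass union-find labeling with 8-connectivity by default
#' (4-connectivity available).
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  next_label <- 0L
  for (c in seq_len(nc)) {
    for (r in seq_len(nr)) {
      if (!mask[r, c]) next
      nb <- integer(0)
      if (r > 1 && mask[r - 1, c]) nb <- c(nb, labels[r - 1, c])
      if (c > 1 && mask[r, c - 1]) nb <- c(nb, labels[r, c - 1])
      if (connectivity == 8 && c > 1) {
        if (r > 1 && mask[r - 1, c - 1]) nb <- c(nb, labels[r - 1, c - 1])
        if (r < nr && mask[r + 1, c - 1]) nb <- c(nb, labels[r + 1, c - 1])
      }
      if (length(nb) == 0) {
        next_label <- next_label + 1L
        parent[next_label] <- next_label
        labels[r, c] <- next_label
      } else {
        roots <- unique(vapply(nb, find, integer(1)))
        keep <- min(roots)
        labels[r, c] <- keep
        for (other in roots[roots != keep]) parent[other] <- keep
      }
    }
  }
  if (next_label > 0L) {
    roots <- vapply(seq_len(next_label), find, integer(1))
    compact <- match(roots, sort(unique(roots)))
    fg <- labels > 0L
    labels[fg] <- compact[labels[fg]]
  }
  labels
}

#' Detect size-gated particles in one channel
#'
#' Thresholds a channel (Otsu by default), labels connected components,
#' discards components whose physical area falls outside the closed
#' interval `area_range_um2` (pixel area = `pixel_size_um^2`, no
#' sub-pixel correction), and computes per-ROI mean intensities in
#' every channel of the image.
#'
#' @param image A [multichannel_image()].
#' @param channel Channel name to segment.
#' @param area_range_um2 Length-2 numeric, inclusive area gate in
#'   square micrometers (the reference settings are 0.2-1 for TH and
#'   0.15-2 for Bassoon/Neuroplastin).
#' @param threshold Intensity threshold; `NULL` (default) uses
#'   [otsu_threshold()].
#' @param connectivity Component connectivity (8 or 4).
#'
#' @return A list of class `particle_set`: `particles` (tibble with
#'   `label`, `channel`, `area_um2`, `centroid_row`, `centroid_col`,
#'   and one `mean_<channel>` column per image channel), `labels`
#'   (integer matrix keeping only retained ROIs), `channel`,
#'   `threshold`, `pixel_size_um`.
#' @export
detect_particles <- function(image, channel, area_range_um2,
                             threshold = NULL, connectivity = 8) {
  stopifnot(inherits(image, "multichannel_image"))
  if (!channel %in% names(image$channels)) {
    stop("unknown channel '", channel, "'", call. = FALSE)
  }
  stopifnot(length(area_range_um2) == 2,
            area_range_um2[1] < area_range_um2[2])
  mat <- image$channels[[channel]]
  if (is.null(threshold)) threshold <- otsu_threshold(mat)
  labels <- label_components(mat > threshold, connectivity = connectivity)
  px_area <- image$pixel_size_um^2

  n_lab <- max(labels)
  if (n_lab == 0) {
    particles <- empty_particles(names(image$channels), channel)
    return(structure(list(particles = particles, labels = labels,
                          channel = channel, threshold = threshold,
                          pixel_size_um = image$pixel_size_um),
                     class = "particle_set"))
  }
  fg <- labels > 0
  lab_vec <- labels[fg]
  idx <- which(fg, arr.ind = TRUE)
  areas_px <- tabulate(lab_vec, nbins = n_lab)
  areas <- areas_px * px_area
  keep <- which(areas >= area_range_um2[1] & areas <= area_range_um2[2])

  cent_r <- as.numeric(tapply(idx[, 1], lab_vec, mean))
  cent_c <- as.numeric(tapply(idx[, 2], lab_vec, mean))
  particles <- tibble::tibble(
    label = seq_len(n_lab), channel = channel,
    area_um2 = areas, centroid_row = cent_r, centroid_col = cent_c)
  for (ch in names(image$channels)) {
    v <- image$channels[[ch]][fg]
    particles[[paste0("mean_", ch)]] <-
      as.numeric(tapply(v, lab_vec, mean))
  }
  particles <- particles[keep, ]
  out_labels <- labels
  out_labels[!(labels %in% keep)] <- 0L
  structure(list(particles = particles, labels = out_labels,
                 channel = channel, threshold = threshold,
                 pixel_size_um = image$pixel_size_um),
            class = "particle_set")
}

empty_particles <- function(channel_names, channel) {
  out <- tibble::tibble(label = integer(), channel = character(),
                        area_um2 = numeric(), centroid_row = numeric(),
                        centroid_col = numeric())
  for (ch in channel_names) out[[paste0("mean_", ch)]] <- numeric()
  out
}

#' Classify TH-positive ROIs by Bassoon content
#'
#' With the default `"overlap"` rule a TH ROI is `BASSOON_POS` if it
#' shares at least one pixel with a detected Bassoon ROI; otherwise it
#' is `BASSOON_NEG` if its mean Bassoon intensity is below
#' `neg_factor` times the mean of all pixels of the Bassoon channel,
#' and `EXCLUDED` otherwise. The `"intensity"` rule instead classifies
#' purely on the global-mean cutoff (at or above = positive, below =
#' negative; nothing is excluded). The classes are mutually exclusive
#' and exhaustive over the TH ROIs.
#'
#' @param th_rois `particle_set` of TH ROIs.
#' @param bassoon_rois `particle_set` of Bassoon ROIs from the same
#'   image.
#' @param image The [multichannel_image()] both came from.
#' @param bassoon_channel Name of the Bassoon channel.
#' @param rule `"overlap"` (default) or `"intensity"`.
#' @param neg_factor Multiple of the image-mean Bassoon intensity below
#'   which a non-overlapping ROI is negative (default 1.0).
#'
#' @return The TH particle tibble with a `th_class` column.
#' @export
classify_th_rois <- function(th_rois, bassoon_rois, image,
                             bassoon_channel = "BASSOON",
                             rule = c("overlap", "intensity"),
                             neg_factor = 1.0) {
  rule <- match.arg(rule)
  stopifnot(inherits(th_rois, "particle_set"),
            inherits(bassoon_rois, "particle_set"),
            inherits(image, "multichannel_image"))
  if (!all(dim(th_rois$labels) == dim(bassoon_rois$labels))) {
    stop("TH and Bassoon ROI label images have mismatched shapes",
         call. = FALSE)
  }
  global_mean <- mean(image$channels[[bassoon_channel]])
  particles <- th_rois$particles
  mean_bsn <- particles[[paste0("mean_", bassoon_channel)]]
  if (nrow(particles) == 0) {
    particles$th_class <- character(0)
    return(particles)
  }
  if (rule == "intensity") {
    particles$th_class <- ifelse(mean_bsn < neg_factor * global_mean,
                                 "BASSOON_NEG", "BASSOON_POS")
    return(particles)
  }
  overlap <- vapply(particles$label, function(l) {
    any(bassoon_rois$labels[th_rois$labels == l] > 0)
  }, logical(1))
  particles$th_class <- ifelse(
    overlap, "BASSOON_POS",
    ifelse(mean_bsn < neg_factor * global_mean, "BASSOON_NEG",
           "EXCLUDED"))
  particles
}

#' Compare target-channel intensity between ROI groups
#'
#' Unpaired two-tailed Student's t-test (pooled variance) and
#' two-sample Kolmogorov-Smirnov test on per-ROI mean intensities of
#' the target channel, plus binned frequency histograms on a shared
#' scale.
#'
#' @param pos,neg Particle tibbles (e.g. the Bassoon-positive and
#'   Bassoon-negative TH ROIs from [classify_th_rois()]).
#' @param target_channel Channel whose per-ROI mean is compared.
#' @param n_bins Histogram bin count.
#'
#' @return List: `t_statistic`, `t_p` (NA with `t_skipped = TRUE` when
#'   either group has fewer than 2 ROIs), `ks_statistic`, `ks_p`,
#'   `n_pos`, `n_neg`, `histograms` (tibble bin_mid, group, count).
#' @export
compare_target_intensity <- function(pos, neg, target_channel = "TARGET",
                                     n_bins = 20) {
  col <- paste0("mean_", target_channel)
  x <- pos[[col]]; y <- neg[[col]]
  if (length(x) == 0 || length(y) == 0) {
    stop("both ROI groups must be non-empty", call. = FALSE)
  }
  t_skipped <- length(x) < 2 || length(y) < 2
  if (t_skipped) {
    t_stat <- NA_real_; t_p <- NA_real_
  } else {
    tt <- t.test(x, y, var.equal = TRUE)
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
  }
  ks <- suppressWarnings(ks.test(x, y))
  breaks <- seq(min(x, y), max(x, y), length.out = n_bins + 1)
  if (breaks[1] == breaks[n_bins + 1]) {
    breaks <- breaks[1] + seq(-0.5, 0.5, length.out = n_bins + 1)
  }
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  bincount <- function(v) {
    tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE),
                       1), n_bins), nbins = n_bins)
  }
  hist <- tibble::tibble(
    bin_mid = rep(mids, 2),
    group = rep(c("BASSOON_POS", "BASSOON_NEG"), each = n_bins),
    count = c(bincount(x), bincount(y)))
  list(t_statistic = t_stat, t_p = t_p, t_skipped = t_skipped,
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       n_pos = length(x), n_neg = length(y), histograms = hist)
}

#' Generate a synthetic stained-synaptosome image with ground truth
#'
#' Places Gaussian spots at random positions with a minimum pairwise
#' separation. Every particle appears in the TH and TARGET channels; a
#' fraction also carries a co-located Bassoon spot. TARGET spot
#' amplitude is drawn with its mean shifted by `effect_size` for
#' Bassoon-positive particles. Gaussian read noise is added to every
#' channel and intensities are clipped at zero. Deterministic per seed.
#'
#' @param n_particles Number of particles to place.
#' @param frac_bassoon_pos Fraction co-located with a Bassoon spot.
#' @param effect_size Additive shift of the mean TARGET amplitude for
#'   Bassoon-positive particles (0 = null).
#' @param noise_sd SD of the Gaussian read noise (intensity units).
#' @param shape Image shape `c(rows, cols)` in pixels.
#' @param pixel_size_um Pixel edge length in micrometers.
#' @param seed Integer seed.
#' @param spot_sigma_px Gaussian spot SD in pixels.
#' @param amplitude Mean peak amplitude of TH/Bassoon spots.
#' @param target_amplitude Mean peak amplitude of TARGET spots.
#' @param amplitude_cv Coefficient of variation of spot amplitudes.
#' @param min_sep_px Minimum center-to-center separation in pixels.
#'
#' @return List: `image` (a [multichannel_image()] with channels `TH`,
#'   `BASSOON`, `TARGET`) and `truth` (tibble with particle centers,
#'   `bassoon_pos` flag and drawn amplitudes).
#' @export
generate_synaptosome_image <- function(n_particles = 60,
                                       frac_bassoon_pos = 0.5,
                                       effect_size = 0,
                                       noise_sd = 2,
                                       shape = c(128, 128),
                                       pixel_size_um = 0.15,
                                       seed = 1L,
                                       spot_sigma_px = 1.8,
                                       amplitude = 100,
                                       target_amplitude = 60,
                                       amplitude_cv = 0.15,
                                       min_sep_px = 8) {
  stopifnot(n_particles >= 1, frac_bassoon_pos >= 0, frac_bassoon_pos <= 1,
            noise_sd >= 0, length(shape) == 2, pixel_size_um > 0)
  nr <- shape[1]; nc <- shape[2]
  margin <- ceiling(3 * spot_sigma_px) + 1
  if (nr - 2 * margin < 1 || nc - 2 * margin < 1) {
    stop("frame too small for the spot size; use a larger shape",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    centers <- matrix(numeric(0), 0, 2)
    attempts <- 0
    while (nrow(centers) < n_particles) {
      attempts <- attempts + 1
      if (attempts > 200 * n_particles) {
        stop("could not place ", n_particles, " particles with ",
             "min_sep_px = ", min_sep_px,
             "; use a larger frame or fewer particles", call. = FALSE)
      }
      cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
      if (nrow(centers) == 0 ||
          all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
              min_sep_px^2)) {
        centers <- rbind(centers, cand)
      }
    }
    n_pos <- round(frac_bassoon_pos * n_particles)
    bassoon_pos <- c(rep(TRUE, n_pos), rep(FALSE, n_particles - n_pos))

    draw_amp <- function(mu) {
      pmax(rnorm(n_particles, mu, amplitude_cv * mu), mu * 0.1)
    }
    th_amp <- draw_amp(amplitude)
    bsn_amp <- draw_amp(amplitude)
    tgt_amp <- pmax(rnorm(n_particles,
                          target_amplitude + effect_size * bassoon_pos,
                          amplitude_cv * target_amplitude),
                    0)

    render <- function(which, amps) {
      img <- matrix(0, nr, nc)
      half <- ceiling(3 * spot_sigma_px)
      for (i in which) {
        r0 <- round(centers[i, 1]); c0 <- round(centers[i, 2])
        rs <- max(1, r0 - half):min(nr, r0 + half)
        cs <- max(1, c0 - half):min(nc, c0 + half)
        patch <- outer(rs - centers[i, 1], cs - centers[i, 2],
                       function(dr, dc) {
                         exp(-(dr^2 + dc^2) / (2 * spot_sigma_px^2))
                       })
        img[rs, cs] <- img[rs, cs] + amps[i] * patch
      }
      if (noise_sd > 0) {
        img <- img + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
      }
      pmax(img, 0)
    }
    channels <- list(
      TH = render(seq_len(n_particles), th_amp),
      BASSOON = render(which(bassoon_pos), bsn_amp),
      TARGET = render(seq_len(n_particles), tgt_amp))
    truth <- tibble::tibble(
      particle = seq_len(n_particles),
      row = centers[, 1], col = centers[, 2],
      bassoon_pos = bassoon_pos,
      th_amplitude = th_amp, bassoon_amplitude = bsn_amp,
      target_amplitude = tgt_amp)
  })
  list(image = multichannel_image(channels, pixel_size_um),
       truth = truth)
}

#' End-to-end quantification of one synaptosome image
#'
#' Convenience wrapper: detects TH and Bassoon ROIs with their
#' respective size gates, classifies the TH ROIs, and compares target
#' intensity between Bassoon-positive and Bassoon-negative groups.
#'
#' @param image A [multichannel_image()].
#' @param th_gate,bassoon_gate Inclusive area gates in square
#'   micrometers.
#' @param target_channel Channel compared between groups.
#' @param rule,neg_factor Passed to [classify_th_rois()].
#'
#' @return List: `th` (classified TH particle tibble), `bassoon`
#'   (Bassoon particle tibble), `comparison` (from
#'   [compare_target_intensity()], or `NULL` if a class is empty).
#' @export
quantify_synaptosomes <- function(image,
                                  th_gate = c(0.2, 1.0),
                                  bassoon_gate = c(0.15, 2.0),
                                  target_channel = "TARGET",
                                  rule = "overlap",
                                  neg_factor = 1.0) {
  th <- detect_particles(image, "TH", th_gate)
  bsn <- detect_particles(image, "BASSOON", bassoon_gate)
  cls <- classify_th_rois(th, bsn, image, rule = rule,
                          neg_factor = neg_factor)
  pos <- cls[cls$th_class == "BASSOON_POS", ]
  neg <- cls[cls$th_class == "BASSOON_NEG", ]
  cmp <- if (nrow(pos) > 0 && nrow(neg) > 0) {
    compare_target_intensity(pos, neg, target_channel)
  } else NULL
  list(th = cls, bassoon = bsn$particles, comparison = cmp)
}
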