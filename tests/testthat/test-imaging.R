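test_that("a two-mode image thresholds strictly between the modes", {
  img <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
  thr <- otsu_threshold(img)
  expect_gt(thr, 0)
  expect_lt(thr, 100)
  expect_true(all(img[img > thr] == 100))
  expect_true(all(img[img <= thr] == 0))
})

test_that("otsu agrees with the exhaustive within-class-variance search", {
  for (s in 1:25) {
    img <- withr::with_seed(s, matrix(runif(32 * 32, 0, 255), 32, 32))
    expect_equal(otsu_threshold(img), otsu_exhaustive_oracle(img))
  }
  bimodal <- withr::with_seed(7, matrix(c(rnorm(500, 20, 5),
                                          rnorm(524, 150, 20)), 32, 32))
  bimodal <- pmax(bimodal, 0)
  expect_equal(otsu_threshold(bimodal), otsu_exhaustive_oracle(bimodal))
})

test_that("constant images have no threshold", {
  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate")
})

test_that("labeling respects the requested connectivity", {
  mask <- matrix(0, 4, 4)
  mask[1, 1] <- 1; mask[2, 2] <- 1  # diagonal touch
  expect_equal(max(label_components(mask, connectivity = 8)), 1)
  expect_equal(max(label_components(mask, connectivity = 4)), 2)
  # a U-shape whose arms merge: union-find must collapse labels
  u <- matrix(0, 5, 5)
  u[1:4, 1] <- 1; u[1:4, 3] <- 1; u[4, 2] <- 1
  expect_equal(max(label_components(u)), 1)
})

test_that("area gating converts pixels to square micrometers inclusively", {
  mat <- matrix(0, 16, 16)
  mat[5:7, 5:7] <- 100  # 9 px square
  img_fine <- multichannel_image(list(TH = mat), pixel_size_um = 0.2)
  ps <- detect_particles(img_fine, "TH", c(0.2, 1.0), threshold = 50)
  expect_equal(nrow(ps$particles), 1)
  expect_equal(ps$particles$area_um2, 9 * 0.04)
  img_coarse <- multichannel_image(list(TH = mat), pixel_size_um = 0.5)
  ps2 <- detect_particles(img_coarse, "TH", c(0.2, 1.0), threshold = 50)
  expect_equal(nrow(ps2$particles), 0)  # 2.25 um2 exceeds every gate
})

test_that("oversized blobs are rejected while planted spots are kept", {
  mat <- matrix(0, 120, 120)
  # 50 in-gate 3x3 spots (0.36 um2 at 0.2 um pixels) on a grid
  k <- 0
  for (i in seq(5, 115, by = 12)) for (j in seq(5, 115, by = 12)) {
    if (k < 50) {
      mat[i:(i + 2), j:(j + 2)] <- 100
      k <- k + 1
    }
  }
  # 5 oversized 10x10 blobs (4 um2, beyond every gate)
  for (j in seq(5, 75, by = 17)) mat[105:114, j:(j + 9)] <- 100
  img <- multichannel_image(list(TH = mat), pixel_size_um = 0.2)
  ps <- detect_particles(img, "TH", c(0.2, 1.0), threshold = 50)
  expect_equal(nrow(ps$particles), 50)
})

test_that("noiseless images are recovered particle for particle", {
  g <- generate_synaptosome_image(n_particles = 10, noise_sd = 0,
                                  seed = 23)
  ps <- detect_particles(g$image, "TH", c(0.2, 1.0))
  expect_equal(nrow(ps$particles), 10)
  ord_truth <- order(g$truth$row, g$truth$col)
  ord_det <- order(ps$particles$centroid_row, ps$particles$centroid_col)
  expect_true(all(abs(ps$particles$centroid_row[ord_det] -
                        g$truth$row[ord_truth]) <= 1))
  expect_true(all(abs(ps$particles$centroid_col[ord_det] -
                        g$truth$col[ord_truth]) <= 1))
})

test_that("generation is deterministic per seed", {
  a <- generate_synaptosome_image(n_particles = 15, seed = 5)
  b <- generate_synaptosome_image(n_particles = 15, seed = 5)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)
})

test_that("particle counts survive translation and affine rescaling", {
  g <- generate_synaptosome_image(n_particles = 25, noise_sd = 1,
                                  seed = 31, shape = c(96, 96))
  base <- nrow(detect_particles(g$image, "TH", c(0.2, 1.0))$particles)
  shifted <- rbind(matrix(0, 5, 96), g$image$channels$TH[1:91, ])
  img_s <- multichannel_image(list(TH = shifted), 0.15)
  expect_equal(nrow(detect_particles(img_s, "TH", c(0.2, 1.0))$particles),
               base)
  img_a <- multichannel_image(list(TH = 3 * g$image$channels$TH + 7), 0.15)
  expect_equal(nrow(detect_particles(img_a, "TH", c(0.2, 1.0))$particles),
               base)
})

test_that("TH ROI classes are exclusive, exhaustive and truth-matching", {
  g <- generate_synaptosome_image(n_particles = 100, noise_sd = 0,
                                  frac_bassoon_pos = 0.4, seed = 41,
                                  shape = c(192, 192))
  q <- quantify_synaptosomes(g$image)
  expect_true(all(q$th$th_class %in%
                    c("BASSOON_POS", "BASSOON_NEG", "EXCLUDED")))
  tab <- table(factor(q$th$th_class,
                      c("BASSOON_POS", "BASSOON_NEG", "EXCLUDED")))
  expect_equal(unname(tab["BASSOON_POS"]), 40L, ignore_attr = TRUE)
  expect_equal(unname(tab["BASSOON_NEG"]), 60L, ignore_attr = TRUE)
  expect_equal(unname(tab["EXCLUDED"]), 0L, ignore_attr = TRUE)
  expect_equal(sum(tab), nrow(q$th))
})

test_that("overlapping and empty-signal ROIs classify as pos and neg", {
  th <- matrix(0, 32, 32); th[5:7, 5:7] <- 100; th[20:22, 20:22] <- 100
  bsn <- matrix(0, 32, 32); bsn[5:7, 5:7] <- 100
  img <- multichannel_image(list(TH = th, BASSOON = bsn), 0.2)
  th_ps <- detect_particles(img, "TH", c(0.2, 1.0), threshold = 50)
  bsn_ps <- detect_particles(img, "BASSOON", c(0.15, 2.0), threshold = 50)
  cls <- classify_th_rois(th_ps, bsn_ps, img)
  cls <- cls[order(cls$centroid_row), ]
  expect_equal(cls$th_class, c("BASSOON_POS", "BASSOON_NEG"))
  # symmetric intensity rule assigns both classes without exclusion
  cls2 <- classify_th_rois(th_ps, bsn_ps, img, rule = "intensity")
  expect_setequal(cls2$th_class, c("BASSOON_POS", "BASSOON_NEG"))
})

test_that("group comparisons match closed-form statistics", {
  pos <- tibble::tibble(mean_TARGET = c(5, 6, 7, 8, 9))
  neg <- tibble::tibble(mean_TARGET = c(4, 5, 5, 6, 7))
  out <- compare_target_intensity(pos, neg)
  x <- pos$mean_TARGET; y <- neg$mean_TARGET
  sp2 <- (4 * var(x) + 4 * var(y)) / 8
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(out$t_statistic, t_hand, tolerance = 1e-10)
  same <- compare_target_intensity(pos, pos)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$ks_statistic, 0)
  tiny <- compare_target_intensity(pos[1, ], neg)
  expect_true(tiny$t_skipped)
  expect_true(is.finite(tiny$ks_statistic))
})

test_that("a planted intensity effect is detected in the right direction", {
  g <- generate_synaptosome_image(n_particles = 60, noise_sd = 2,
                                  effect_size = 25, seed = 51)
  q <- quantify_synaptosomes(g$image)
  expect_gt(q$comparison$t_statistic, 0)
  expect_lt(q$comparison$t_p, 0.05)
})
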