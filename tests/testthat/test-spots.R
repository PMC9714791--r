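# Image-quantification pipeline: background, nuclei, texture, spot
# filters, densities.  All fixtures are generated in code.

blob_image <- function(nr = 96, nc = 96, centers, amp = 0.4, sigma = 4,
                       base = 0.05) {
  img <- matrix(base, nr, nc)
  rg <- matrix(seq_len(nr), nr, nc)
  cg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    d2 <- (rg - centers[i, 1])^2 + (cg - centers[i, 2])^2
    img <- img + amp * exp(-d2 / (2 * sigma^2))
  }
  img
}

test_that("remove_background flattens constants and slow ramps", {
  expect_equal(remove_background(matrix(0.3, 40, 40)), matrix(0, 40, 40))
  expect_error(remove_background(array(0, c(4, 4, 2))), "2-D")

  # blobs on a linear ramp: ramp removed, blob peaks preserved in place
  centers <- rbind(c(30, 30), c(70, 64))
  ramp <- outer(seq(0, 0.15, length.out = 96), seq(0, 0.1, length.out = 96), "+")
  img <- blob_image(centers = centers) + ramp
  out <- remove_background(img)
  for (i in 1:2) {
    win <- out[centers[i, 1] + (-6:6), centers[i, 2] + (-6:6)]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - 7)), 1)     # peak shift <= 1 px
  }
  # far from the blobs the ramp is essentially gone
  flat <- out[1:10, 1:10]
  expect_lt(max(flat) - min(flat), 0.02)
  # idempotence: a second pass changes little
  out2 <- remove_background(out)
  expect_lt(max(abs(out2 - out)), 0.02)
})

test_that("detect_nuclei honours the area floor and recovers the truth", {
  # blank image: no nuclei, not an error
  blank <- matrix(0, 64, 64)
  expect_equal(attr(detect_nuclei(blank), "n"), 0L)

  # a single blob below the 200-px floor is rejected
  small <- matrix(0.02, 64, 64)
  rg <- matrix(seq_len(64), 64, 64)
  cg <- t(rg)
  small[(rg - 32)^2 + (cg - 32)^2 <= 48] <- 0.5   # ~150 px disk
  expect_equal(attr(detect_nuclei(small), "n"), 0L)

  # synthetic truth: all nuclei above the floor are recovered
  sim <- simulate_images(image_sim_config(n_nuclei = 10L, seed = 29))
  lab <- detect_nuclei(remove_background(sim$dapi))
  expect_equal(attr(lab, "n"), 10L)
  # detected labels cover the truth centres
  for (i in seq_len(10)) {
    px <- which(sim$nuclei_mask == i, arr.ind = TRUE)
    ctr <- round(colMeans(px))
    expect_gt(lab[ctr[1], ctr[2]], 0L)
  }
})

test_that("spot_texture is a calibrated matched filter", {
  expect_error(spot_texture(matrix(0, 8, 8), scale_px = 0.5), "scale")
  flat <- spot_texture(matrix(0.4, 48, 48))
  expect_lt(max(abs(flat)), 1e-10)

  # response peaks at the centre of a matched spot, near the amplitude
  img <- blob_image(64, 64, rbind(c(32, 32)), amp = 0.5, sigma = 3)
  tex <- spot_texture(img, scale_px = 3)
  pk <- which(tex == max(tex), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(32, 32))
  expect_equal(max(tex), 0.5, tolerance = 0.05)

  # at SNR >= 5, truth spot centres out-score background locations
  cfg <- image_sim_config(spot_amplitude = 0.25, noise_sd = 0.05,
                          photon_gain = 1e6, seed = 31)
  sim <- simulate_images(cfg)
  tex <- spot_texture(sim$spot_channel)
  at_spots <- tex[cbind(round(sim$spot_truth$row), round(sim$spot_truth$col))]
  set.seed(1)
  bg <- which(sim$nuclei_mask == 0)
  d2 <- outer(((bg - 1) %% nrow(tex)) + 1, sim$spot_truth$row, "-")^2 +
    outer(((bg - 1) %/% nrow(tex)) + 1, sim$spot_truth$col, "-")^2
  far <- bg[sqrt(apply(d2, 1, min)) > 15]
  expect_gt(min(at_spots), max(quantile(tex[far], 0.999), 0.1))
})

test_that("segment_spots reaches 0.9 precision/recall on SNR >= 10 truth", {
  hits <- 0; total_p <- 0; total_r <- 0
  for (s in 1:2) {
    sim <- simulate_images(image_sim_config(seed = 200 + s))
    nuc <- detect_nuclei(remove_background(sim$dapi))
    spots <- segment_spots(sim$spot_channel, nuc)
    m <- match_spots(spots, sim$spot_truth)
    expect_gte(m$precision, 0.9)
    expect_gte(m$recall, 0.9)
    # every retained record satisfies the filters by direct re-check
    expect_true(all(spots$area_px >= 5))
    expect_true(all(spots$mean_intensity >= 2 * mean(sim$spot_channel)))
    expect_true(all(spots$ring_contrast >= 1.3))
    # nuclear + extranuclear = total
    expect_equal(sum(spots$is_nuclear) + sum(!spots$is_nuclear), nrow(spots))
  }
  # blank channel yields an empty record set
  expect_equal(nrow(segment_spots(matrix(0.05, 64, 64), NULL)), 0L)
})

test_that("a spot embedded in an equally bright plateau fails the ring rule", {
  bump <- blob_image(96, 96, rbind(c(50, 50)), amp = 0.3, sigma = 3,
                     base = 0)
  on_plateau <- matrix(0.7, 96, 96) + bump       # bright everywhere
  iso <- matrix(0.05, 96, 96) + bump             # same bump, dim background
  # intensity_factor = 1 so only the ring rule separates the two cases
  sp_iso <- segment_spots(iso, NULL, intensity_factor = 1)
  expect_equal(nrow(sp_iso), 1L)
  expect_gte(sp_iso$ring_contrast, 1.3)
  # the embedded bump is excluded by the 1.3x ring-contrast rule
  sp_pl <- segment_spots(on_plateau, NULL, intensity_factor = 1)
  expect_equal(nrow(sp_pl), 0L)
})

test_that("raising any filter threshold never increases the spot count", {
  sim <- simulate_images(image_sim_config(seed = 37))
  nuc <- detect_nuclei(remove_background(sim$dapi))
  n0 <- nrow(segment_spots(sim$spot_channel, nuc))
  expect_lte(nrow(segment_spots(sim$spot_channel, nuc, texture_cut = 0.35)), n0)
  expect_lte(nrow(segment_spots(sim$spot_channel, nuc, min_area = 20)), n0)
  expect_lte(nrow(segment_spots(sim$spot_channel, nuc, intensity_factor = 6)), n0)
  expect_lte(nrow(segment_spots(sim$spot_channel, nuc, ring_factor = 4)), n0)
})

test_that("spot_density performs the unit arithmetic", {
  spots <- data.frame(is_nuclear = rep(c(TRUE, FALSE), c(40, 60)))
  # 100 x 100 px at 10 um/px = exactly 1 mm^2
  region <- matrix(TRUE, 100, 100)
  d <- spot_density(spots, region, pixel_size_um = 10)
  expect_equal(d$region_area_mm2, 1)
  expect_equal(d$nuclear_per_mm2, 40)
  expect_equal(d$extranuclear_per_mm2, 60)
  d0 <- spot_density(spots[0, , drop = FALSE], region, pixel_size_um = 10)
  expect_equal(d0$nuclear_per_mm2 + d0$extranuclear_per_mm2, 0)
  expect_error(spot_density(spots, matrix(FALSE, 4, 4), 10), "zero area")
})

test_that("measured extranuclear density recovers the configured rate", {
  rate <- 2000   # spots per mm^2 of non-nuclear area
  tot_ext <- 0; tot_area <- 0; expected <- 0
  for (s in 1:12) {
    cfg <- image_sim_config(image_shape = c(192L, 192L), n_nuclei = 6L,
                            extranuclear_spot_rate = rate,
                            nuclear_spot_rate = 0.5, seed = 400 + s)
    sim <- simulate_images(cfg)
    nuc <- detect_nuclei(remove_background(sim$dapi))
    spots <- segment_spots(sim$spot_channel, nuc)
    ext_region <- sim$nuclei_mask == 0
    d <- spot_density(spots[!spots$is_nuclear, ], ext_region,
                      pixel_size_um = cfg$pixel_size_um)
    tot_ext <- tot_ext + d$n_extranuclear
    tot_area <- tot_area + d$region_area_mm2
    expected <- expected + rate * d$region_area_mm2
  }
  # Poisson oracle: total count within 3 SD of the configured rate
  expect_lt(abs(tot_ext - expected), 3 * sqrt(expected))
  expect_equal(tot_ext / tot_area, rate, tolerance = 3 * sqrt(expected) / expected)
})
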