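test_that("baseline envelope tracks constants, offsets and slow ramps but not transients", {
  fs <- 5
  n <- 600
  const <- rep(50, n)
  expect_equal(baseline_envelope(const, fs), const, tolerance = 1e-9)
  # additive offset equivariance
  x <- 50 + 5 * sin(2 * pi * (0:(n - 1)) / n)
  expect_equal(baseline_envelope(x + 7, fs), baseline_envelope(x, fs) + 7,
               tolerance = 1e-9)
  # slow ramp + sparse transients: envelope follows the ramp
  ramp <- seq(100, 110, length.out = n)
  tr <- numeric(n)
  k <- dexp_kernel(fs, 1, 2)
  for (i in c(150, 400)) tr[i:(i + length(k) - 1)] <- 40 * k
  F0 <- baseline_envelope(ramp + tr[1:n], fs)
  expect_lt(max(abs(F0 - ramp)), 4)            # < amplitude / 10
  expect_error(baseline_envelope(c(1, 2), fs), "3 time points")
})

test_that("mode bias correction recovers a known offset and is idempotent", {
  set.seed(11)
  n <- 2000
  resid <- rnorm(n, 0, 2)
  F <- 100 + resid + 5                     # baseline estimate low by 5
  F0 <- rep(100, n)
  F0c <- mode_bias_correct(F, F0)
  expect_equal(mean(F0c - F0), 5, tolerance = 0.5)
  # residual mode already zero -> offset ~ 0
  F0cc <- mode_bias_correct(F, F0c)
  expect_equal(mean(F0cc - F0c), 0, tolerance = 0.5)
  # degenerate constant residuals
  expect_equal(mode_bias_correct(rep(3, 10), rep(1, 10)), rep(3, 10))
})

test_that("dF/F follows the defining formula and masks bad baselines", {
  F0 <- c(100, 100, 100)
  expect_equal(compute_dff(c(100, 200, 115), F0), c(0, 100, 15))
  expect_warning(out <- compute_dff(matrix(1:4, 2), matrix(c(-1, 2, -1, 2), 2)),
                 "non-positive")
  expect_true(all(is.na(out[1, ])))
})

test_that("the stained mask is scale invariant and matches the synthetic scene", {
  cfg <- small_cfg(fov = 64L, seed = 4)
  sc <- generate_scene(cfg)
  sim <- simulate_fluorescence(cfg, sc, generate_speed_trace(cfg))
  mean_img <- apply(sim$green$frames[, , 1:10], c(1, 2), mean)
  mask <- stained_mask(mean_img)
  expect_gt(caflux:::jaccard_index(mask, sc$stained), 0.8)
  expect_identical(stained_mask(mean_img * 37), mask)
  expect_error(stained_mask(matrix(0, 4, 4)), "featureless")
})

test_that("active-segment detection applies the three rules bit-exactly", {
  h <- 24; Tn <- 6
  mk_dff <- function() {
    d <- array(0, c(h, h, Tn))
    structure(list(dff = d, fs = 5, stained_mask = matrix(TRUE, h, h)),
              class = "dff_movie")
  }
  block <- function(d, rows, cols, frames, val = 20) {
    for (t in frames) d$dff[rows, cols, t] <- val
    d
  }
  # 4x4 = 16 pixels is NOT larger than 16 -> rejected
  d16 <- block(mk_dff(), 1:4, 1:4, 1:6)
  expect_equal(nrow(detect_active_segments(d16)$segments), 0)
  # 17 pixels for >= 3 frames -> accepted
  d17 <- block(mk_dff(), 1:4, 1:4, 1:6)
  d17$dff[5, 1, ] <- 20
  segs <- detect_active_segments(d17)
  expect_gt(nrow(segs$segments), 0)
  expect_true(all(segs$segments$n_pixels == 17))
  # 30-pixel cluster lasting only 2 frames -> rejected
  d2f <- block(mk_dff(), 1:5, 1:6, 1:2)
  expect_equal(nrow(detect_active_segments(d2f)$segments), 0)
  # dF/F exactly 15.0 is retained (threshold is >=)
  d15 <- block(mk_dff(), 1:5, 1:6, 1:3, val = 15)
  expect_gt(nrow(detect_active_segments(d15)$segments), 0)
  # just below threshold -> rejected
  d14 <- block(mk_dff(), 1:5, 1:6, 1:3, val = 14.999)
  expect_equal(nrow(detect_active_segments(d14)$segments), 0)
})

test_that("clusters are linked by 8-connectivity within a frame and overlap across frames", {
  h <- 30
  d <- array(0, c(h, h, 4))
  # two diagonal-touching blocks form one cluster of 18 px (> 16)
  d[1:3, 1:3, 1:3] <- 20
  d[4:6, 4:6, 1:3] <- 20
  dm <- structure(list(dff = d, fs = 5, stained_mask = matrix(TRUE, h, h)),
                  class = "dff_movie")
  segs <- detect_active_segments(dm)
  expect_equal(unique(segs$segments$n_pixels), 18)
  expect_equal(length(unique(segs$segments$segment)), 1)
})

test_that("active area is the retained fraction of the stained area", {
  h <- 20
  stained <- matrix(FALSE, h, h); stained[1:10, ] <- TRUE   # 200 px
  d <- array(0, c(h, h, 5))
  d[1:5, 1:20, 2:4] <- 30                                   # 100 px active
  dm <- structure(list(dff = d, fs = 5, stained_mask = stained),
                  class = "dff_movie")
  segs <- detect_active_segments(dm)
  aa <- active_area_trace(segs)
  expect_equal(aa$active_area_pct, c(0, 50, 50, 50, 0))
  # no segments -> all zero; empty stained mask -> error
  dm0 <- structure(list(dff = array(0, c(h, h, 3)), fs = 5,
                        stained_mask = stained), class = "dff_movie")
  expect_true(all(active_area_trace(detect_active_segments(dm0))$active_area_pct == 0))
  expect_error(active_area_trace(segs, matrix(FALSE, h, h)), "empty")
})

test_that("lowering thresholds never decreases the active area (monotonicity)", {
  cfg <- small_cfg(duration_s = 40, fs_raw = 10, fov = 32L,
                   mean_quiet_s = 10, mean_run_s = 10,
                   domain_radius_px = 10, soma_radius_px = 3, seed = 9)
  sp <- generate_speed_trace(cfg)
  sc <- generate_scene(cfg)
  cam <- apply_camera(simulate_fluorescence(cfg, sc, sp), cfg)
  d <- dff_movie_pipeline(cam$green, stained_mask = sc$stained)
  a_hi <- active_area_trace(detect_active_segments(d, thr = 20, min_pixels = 20))
  a_lo <- active_area_trace(detect_active_segments(d, thr = 10, min_pixels = 8))
  expect_true(all(a_lo$active_area_pct >= a_hi$active_area_pct - 1e-12))
})
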