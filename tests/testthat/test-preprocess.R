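test_that("temporal binning sums batches, drops the remainder and conserves intensity", {
  m <- ca_movie(array(rep(1:17, each = 4), c(2, 2, 17)), fs = 30, "green")
  b <- temporal_bin(m, 5)
  expect_equal(dim(b$frames)[3], 3)            # floor(17 / 5)
  expect_equal(b$fs, 6)
  expect_equal(b$frames[1, 1, ], c(sum(1:5), sum(6:10), sum(11:15)))
  expect_equal(sum(b$frames), sum(m$frames[, , 1:15]))
  # batch 1 is the identity; constant value c bins to 5c
  expect_identical(temporal_bin(m, 1), m)
  const <- ca_movie(array(3, c(2, 2, 10)), 30, "green")
  expect_true(all(temporal_bin(const, 5)$frames == 15))
  expect_error(temporal_bin(m, 100), "exceeds")
})

test_that("reference denoising reproduces low-rank stacks and reduces noise variance", {
  set.seed(5)
  img <- matrix(runif(256, 10, 100), 16, 16)
  prof <- 1 + 0.3 * sin(seq(0, 10, length.out = 40))
  rank1 <- ca_movie(array(outer(as.numeric(img), prof), c(16, 16, 40)),
                    5, "red")
  den <- denoise_reference(rank1, n_components = 2, sigma_px = 0)
  expect_lt(max(abs(den$frames - rank1$frames)), 1e-8)
  # static image + white noise: residual variance shrinks
  noisy <- rank1
  noisy$frames <- noisy$frames + array(rnorm(length(noisy$frames), 0, 5),
                                       dim(noisy$frames))
  noisy$frames <- pmax(noisy$frames, 0)
  den2 <- denoise_reference(noisy, n_components = 5, sigma_px = 0)
  expect_lt(var(as.numeric(den2$frames - rank1$frames)),
            var(as.numeric(noisy$frames - rank1$frames)))
  expect_warning(denoise_reference(rank1, n_components = 100), "rank")
})

test_that("shift estimation recovers injected integer drift exactly and is idempotent", {
  cfg <- small_cfg(fov = 64L, max_shift_px = 5L, seed = 2)
  sp <- generate_speed_trace(cfg)
  sim <- simulate_fluorescence(cfg, generate_scene(cfg), sp)
  cam <- apply_camera(sim, cfg)
  rd <- denoise_reference(cam$red, n_components = 50)
  sh <- estimate_shifts(rd)
  expect_identical(sh$dy_px, cam$shifts$dy_px)
  expect_identical(sh$dx_px, cam$shifts$dx_px)
  # residual shifts after correction are zero
  sh2 <- estimate_shifts(apply_shifts(rd, sh))
  expect_true(all(sh2$dy_px == 0 & sh2$dx_px == 0))
  # identical frames -> all zero
  still <- ca_movie(array(rep(matrix(runif(64), 8, 8), 5), c(8, 8, 5)),
                    5, "red")
  sh3 <- estimate_shifts(still)
  expect_true(all(sh3$dy_px == 0 & sh3$dx_px == 0))
})

test_that("applying shifts undoes a translation up to edge pixels and raises template correlation", {
  set.seed(8)
  img <- matrix(runif(900), 30, 30)
  fr <- array(0, c(30, 30, 3))
  shifts <- data.frame(frame = 0:2, dy_px = c(0L, 2L, -3L),
                       dx_px = c(0L, -1L, 2L))
  for (t in 1:3) fr[, , t] <- caflux:::translate_int(img, shifts$dy_px[t],
                                                     shifts$dx_px[t])
  m <- ca_movie(fr, 5, "green")
  fixed <- apply_shifts(m, shifts)
  inner_r <- 5:26; inner_c <- 5:26
  for (t in 1:3)
    expect_equal(fixed$frames[inner_r, inner_c, t], img[inner_r, inner_c])
  # zero shifts = identity
  z <- data.frame(frame = 0:2, dy_px = 0L, dx_px = 0L)
  expect_identical(apply_shifts(m, z)$frames, m$frames)
  expect_error(apply_shifts(m, shifts[1:2, ]), "length")
  # correction raises frame-template correlation
  r_before <- cor(as.numeric(m$frames[, , 2]), as.numeric(img))
  r_after <- cor(as.numeric(fixed$frames[, , 2]), as.numeric(img))
  expect_gt(r_after, r_before)
})

test_that("the Anscombe pair stabilizes Poisson variance and round-trips", {
  expect_equal(anscombe(0), 2 * sqrt(0.375))
  for (x in c(0, 1, 10, 1e4))
    expect_equal(inverse_anscombe(anscombe(x)), x, tolerance = 1e-12)
  expect_error(anscombe(-1), "non-negative")
  set.seed(3)
  draws <- rpois(1e5, 50)
  expect_equal(sd(anscombe(draws)), 1, tolerance = 0.1)
})

test_that("patch-SVD reconstructs exact low-rank movies and its blend weights cover every pixel", {
  set.seed(4)
  h <- 24; Tn <- 30
  A <- matrix(runif(h * h * 2), h * h, 2)
  C <- matrix(runif(2 * Tn, 0.5, 1.5), 2, Tn)
  m <- ca_movie(array(A %*% C, c(h, h, Tn)), 5, "green")
  den <- patch_svd_denoise(m, patch = 12, overlap = 6, rank = 4,
                           sigma_spatial = 0, transform = FALSE)
  expect_lt(max(abs(den$frames - m$frames)), 1e-8)
  # a constant movie passes through unchanged whatever the tiling
  # (weights summing to one at every pixel leave constants invariant)
  const <- ca_movie(array(5, c(24, 24, 10)), 5, "green")
  out <- patch_svd_denoise(const, patch = 10, overlap = 3, rank = 1,
                           sigma_spatial = 0, transform = FALSE)
  expect_equal(out$frames, const$frames, tolerance = 1e-10)
  expect_warning(patch_svd_denoise(m, patch = 12, rank = 1000), "clipped")
  expect_error(patch_svd_denoise(m, patch = 12, overlap = 12), "overlap")
})

test_that("the denoising chain lowers MSE against the clean truth on a noisy synthetic movie", {
  cfg <- small_cfg(duration_s = 40, fs_raw = 10, fov = 32L,
                   mean_quiet_s = 10, mean_run_s = 10,
                   domain_radius_px = 10, soma_radius_px = 3, seed = 6)
  sp <- generate_speed_trace(cfg)
  sim <- simulate_fluorescence(cfg, generate_scene(cfg), sp)
  cam <- apply_camera(sim, cfg)
  den <- patch_svd_denoise(cam$green, patch = 32, rank = 8)
  mse_raw <- mean((cam$green$frames - sim$green$frames)^2)
  mse_den <- mean((den$frames - sim$green$frames)^2)
  expect_lt(mse_den, mse_raw)
})
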