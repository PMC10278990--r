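test_that("speed traces have the configured sampling, non-negative speed and quiescent zeros", {
  cfg <- small_cfg(duration_s = 600, fs_raw = 30, paired_prob = 0)
  sp <- generate_speed_trace(cfg)
  expect_equal(nrow(sp$speed), 18000)          # 600 s x 30 Hz
  expect_true(all(sp$speed$speed_cm_s >= 0))
  # speed is exactly zero inside quiescence intervals
  q <- sp$episodes[sp$episodes$label == "quiescence", ]
  tt <- sp$speed$time_s
  for (i in seq_len(nrow(q))) {
    sel <- tt >= q$start_s[i] & tt < q$end_s[i]
    expect_true(all(sp$speed$speed_cm_s[sel] == 0))
  }
})

test_that("pairing control works: prob 0 separates runs by > 30 s, prob 1 yields a close pair", {
  sp0 <- generate_speed_trace(small_cfg(duration_s = 300, paired_prob = 0))
  runs <- sp0$episodes[sp0$episodes$label == "locomotion", ]
  if (nrow(runs) > 1) {
    gaps <- runs$start_s[-1] - runs$end_s[-nrow(runs)]
    expect_true(all(gaps > 30))
  }
  expect_equal(nrow(sp0$pairs), 0)

  sp1 <- generate_speed_trace(small_cfg(duration_s = 300, paired_prob = 1))
  expect_gt(nrow(sp1$pairs), 0)
  expect_true(all(sp1$pairs$gap_s < 30))
})

test_that("generators are deterministic in (config, seed) and leave the caller's RNG alone", {
  cfg <- small_cfg(seed = 17, n_neuro_units = 2L)
  set.seed(999); before <- runif(1)
  a <- generate_speed_trace(cfg)
  b <- generate_speed_trace(cfg)
  expect_identical(a, b)
  sc1 <- generate_scene(cfg)
  sc2 <- generate_scene(cfg)
  expect_identical(sc1, sc2)
  set.seed(999); expect_identical(runif(1), before)
})

test_that("scenes satisfy the mask contracts", {
  cfg <- small_cfg(fov = 96L, n_astro = 2L, n_neuro_units = 3L)
  sc <- generate_scene(cfg)
  expect_length(sc$astro, 2)
  for (cell in sc$astro) {
    expect_true(all(cell$soma <= cell$domain))          # soma inside domain
    expect_lt(sum(cell$soma), sum(cell$domain))
    expect_true(!any(cell$processes & cell$soma))
  }
  # domains pairwise disjoint
  expect_lte(max(sc$astro[[1]]$domain + sc$astro[[2]]$domain), 1)
  for (fp in sc$neuro_footprints) {
    expect_true(all(fp >= 0))
    expect_equal(max(fp), 1)
  }
  expect_error(generate_scene(small_cfg(fov = 16L, n_astro = 4L)),
               "placement")
})

test_that("clean fluorescence realizes the configured kinetics", {
  cfg <- small_cfg(duration_s = 50, fs_raw = 10, mean_quiet_s = 10,
                   mean_run_s = 15, soma_amp = 3, soma_delay_s = 4.7,
                   osc_amp = 0, gain = 0, read_sd = 0)
  sp <- generate_speed_trace(cfg)
  sc <- generate_scene(cfg)
  sim <- simulate_fluorescence(cfg, sc, sp)
  p <- sim$truth$astro[[1]]$proc_trace
  s <- sim$truth$astro[[1]]$soma_trace
  # soma peak = amplification x process peak (no oscillation, no noise)
  expect_equal(max(s), 3 * max(p), tolerance = 1e-10)
  # onset-time difference equals the configured centripetal delay
  t_p <- (which(p > 0.15 * max(p))[1] - 1) / cfg$fs_raw
  t_s <- (which(s > 0.15 * max(s))[1] - 1) / cfg$fs_raw
  expect_equal(t_s - t_p, 4.7, tolerance = 1 / cfg$fs_raw + 1e-9)
  # red channel is static morphology
  expect_equal(sim$red$frames[, , 1], sim$red$frames[, , dim(sim$red$frames)[3]])
})

test_that("depletion scales the second paired response by alpha (and not at alpha = 1)", {
  for (alpha in c(0.4, 1)) {
    cfg <- small_cfg(duration_s = 70, fs_raw = 10, mean_quiet_s = 12,
                     mean_run_s = 8, paired_prob = 1, paired_gap_s = 15,
                     depletion_alpha = alpha, osc_amp = 0,
                     gain = 0, read_sd = 0, seed = 3)
    sp <- generate_speed_trace(cfg)
    expect_gt(nrow(sp$pairs), 0)
    sim <- simulate_fluorescence(cfg, generate_scene(cfg), sp)
    p <- sim$truth$astro[[1]]$proc_trace
    fs <- cfg$fs_raw
    pk <- function(a, b) max(p[round(a * fs):round(b * fs)])
    pair <- sp$pairs[1, ]
    r1 <- pk(pair$first_start_s, pair$second_start_s)
    r2 <- pk(pair$second_start_s, min(pair$second_end_s + 10, cfg$duration_s))
    expect_equal(r2 / r1, alpha, tolerance = 0.05)
  }
})

test_that("the camera model has Poisson-Gaussian statistics and bounded identical shifts", {
  cfg <- small_cfg(duration_s = 4, fs_raw = 5, fov = 100L, n_astro = 0L,
                   gain = 1, read_sd = 2, max_shift_px = 3L)
  # flat scene: variance of a flat region ~ gain * mean + read_sd^2
  flat <- list(green = ca_movie(array(100, c(100, 100, 20)), 5, "green"),
               red = ca_movie(array(50, c(100, 100, 20)), 5, "red"))
  cam <- apply_camera(flat, cfg)
  expect_true(all(cam$green$frames >= 0))
  expect_true(all(cam$green$frames == round(cam$green$frames)))
  v <- var(as.numeric(cam$green$frames[, , 1]))
  expect_equal(v, 100 + 4, tolerance = 0.05 * 104)
  expect_true(all(abs(cam$shifts$dy_px) <= 3))
  expect_identical(cam$shifts$dy_px[1], 0L)

  # noiseless limit: gain 0, no read noise, no shifts -> identity
  cfg0 <- small_cfg(duration_s = 4, fs_raw = 5, fov = 20L, n_astro = 0L,
                    gain = 0, read_sd = 0, max_shift_px = 0L)
  still <- list(green = ca_movie(array(7, c(20, 20, 20)), 5, "green"),
                red = ca_movie(array(3, c(20, 20, 20)), 5, "red"))
  cam0 <- apply_camera(still, cfg0)
  expect_equal(cam0$green$frames, still$green$frames)
  expect_true(all(cam0$shifts$dy_px == 0 & cam0$shifts$dx_px == 0))
})

test_that("configuration invariants are enforced", {
  expect_error(scenario_config(duration_s = -1), "duration")
  expect_error(scenario_config(depletion_alpha = 0), "alpha")
  expect_error(scenario_config(depletion_alpha = 1.2), "alpha")
  expect_error(scenario_config(osc_freq_hz = 0.5), "osc_freq")
  expect_error(scenario_config(paired_gap_s = 35), "paired_gap")
  expect_error(scenario_config(n_astro = -1), "counts")
})
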