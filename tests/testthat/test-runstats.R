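test_that("episode segmentation partitions time and matches generator truth", {
  # all-zero speed -> one quiescence episode
  sp0 <- data.frame(time_s = seq(0, 9.9, by = 0.1), speed_cm_s = 0)
  e0 <- segment_episodes(sp0)
  expect_equal(nrow(e0), 1)
  expect_identical(e0$label, "quiescence")
  expect_equal(e0$end_s - e0$start_s, 10)

  sp <- generate_speed_trace(small_cfg(duration_s = 200, fs_raw = 10,
                                       mean_quiet_s = 35, mean_run_s = 12,
                                       seed = 7))
  e <- segment_episodes(sp$speed)
  # partition: durations sum to the recording, labels alternate
  expect_equal(sum(e$end_s - e$start_s), 200, tolerance = 1e-9)
  expect_true(all(e$label[-1] != e$label[-nrow(e)]))
  # boundaries match the generated intervals closely
  truth <- sp$episodes[sp$episodes$label == "locomotion", ]
  est <- e[e$label == "locomotion", ]
  expect_equal(nrow(est), nrow(truth))
  expect_lt(max(abs(est$start_s - truth$start_s)), 1.5)

  # two bursts closer than merge_gap_s form one episode
  v <- rep(0, 100); v[20:30] <- 5; v[33:43] <- 5
  spm <- data.frame(time_s = seq(0, 9.9, by = 0.1), speed_cm_s = v)
  em <- segment_episodes(spm, merge_gap_s = 0.5)
  expect_equal(sum(em$label == "locomotion"), 1)
})

test_that("episode means label and average per episode", {
  e <- data.frame(start_s = c(0, 5, 10), end_s = c(5, 10, 15),
                  label = c("quiescence", "locomotion", "quiescence"))
  fs <- 2
  x <- rep(c(0, 1, 0), each = 10)                # indicator of locomotion
  m <- episode_means(x, fs, e)
  expect_equal(m$mean, c(0, 1, 0))
  const <- episode_means(rep(4.2, 30), fs, e)
  expect_true(all(const$mean == 4.2))
  # permuting episode order preserves the multiset of means
  m2 <- episode_means(x, fs, e[c(2, 1, 3), ])
  expect_equal(sort(m2$mean), sort(m$mean))
})

test_that("Q/L ratio has the defining special cases", {
  e <- data.frame(start_s = c(0, 5), end_s = c(5, 10),
                  label = c("quiescence", "locomotion"))
  fs <- 2
  same <- rep(3, 20)
  expect_equal(ql_ratio(same, fs, e), 1)
  only_l <- c(rep(0, 10), rep(2, 10))
  expect_equal(ql_ratio(only_l, fs, e), 0)
  expect_true(is.na(ql_ratio(c(rep(1, 10), rep(0, 10)), fs, e)))
})

test_that("cross-correlation recovers identity, sign and injected lags", {
  set.seed(51)
  fs <- 6
  n <- 600
  s <- pmax(0, stats::filter(rnorm(n), rep(1, 25), circular = TRUE))
  s <- as.numeric(s)
  xc <- speed_dff_crosscorr(s, s, fs)
  expect_equal(xc$r, 1, tolerance = 1e-9)
  expect_equal(xc$lag_s, 0)
  neg <- speed_dff_crosscorr(-s, s, fs, extremum = "absmax")
  expect_equal(neg$r, -1, tolerance = 1e-9)
  expect_equal(neg$lag_s, 0)
  for (lag_s in c(0, 1, 2.5, 5)) {
    k <- round(lag_s * fs)
    x <- c(rep(0, k), s[1:(n - k)])
    xc <- speed_dff_crosscorr(x, s, fs)
    expect_equal(xc$lag_s, k / fs, tolerance = 1 / fs + 1e-9)
  }
  expect_error(speed_dff_crosscorr(rep(1, 10), rep(1, 10), fs), "variance")
})

test_that("paired-run detection enforces the strict 30 s bound and greedy pairing", {
  mk_e <- function(gaps) {
    # runs of 10 s separated by the given gaps
    starts <- 10
    for (g in gaps) starts <- c(starts, tail(starts, 1) + 10 + g)
    data.frame(start_s = starts, end_s = starts + 10, label = "locomotion")
  }
  e <- mk_e(c(10, 40))
  p <- find_paired_runs(e)
  expect_equal(nrow(p), 1)
  expect_equal(p$gap_s, 10)
  # gap exactly 30 s -> excluded
  e30 <- mk_e(c(30))
  expect_equal(nrow(find_paired_runs(e30)), 0)
  e29 <- mk_e(c(29.99))
  expect_equal(nrow(find_paired_runs(e29)), 1)
  # no runs -> empty
  eq <- data.frame(start_s = 0, end_s = 100, label = "quiescence")
  expect_equal(nrow(find_paired_runs(eq)), 0)
  # greedy: three runs with small gaps pair (1,2) and leave 3
  e3 <- mk_e(c(5, 5))
  expect_equal(nrow(find_paired_runs(e3)), 1)
})

test_that("the paired-run ratio is the second/first response ratio", {
  fs <- 2
  x <- rep(0, 200)
  x[21:40] <- 10          # response to run 1 (t = 10..20 s)
  x[101:120] <- 3.2       # response to run 2 (t = 50..60 s)
  pair <- data.frame(first_start_s = 10, first_end_s = 20,
                     second_start_s = 50, second_end_s = 60, gap_s = 30)
  r <- paired_run_ratio(x, fs, pair)
  expect_equal(r$prr_peak, 0.32)
  # identical responses -> 1
  x2 <- x; x2[101:120] <- 10
  expect_equal(paired_run_ratio(x2, fs, pair)$prr_peak, 1)
  # zero first response -> NA
  expect_true(is.na(paired_run_ratio(rep(0, 200), fs, pair)$prr_peak))
})

test_that("Mann-Whitney exact branch equals full enumeration and wilcox.test agrees", {
  # hand-checkable example: complete separation of 3 vs 3
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 2 / 20)               # two-sided; one-sided 1/20
  # identical samples -> p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # U_a + U_b = n_a * n_b
  a <- c(3, 9, 1, 7); b <- c(2, 8, 5)
  expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U, 12)
  # exact branch vs independent full enumeration, all n_a + n_b <= 10
  set.seed(61)
  for (rep in 1:25) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    vals <- sample(1:6, na + nb, replace = TRUE)  # ties included
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    mw <- mann_whitney(a, b)
    expect_identical(mw$method, "exact")
    r <- rank(vals); mu <- na * nb / 2
    Us <- apply(utils::combn(na + nb, na), 2, function(idx)
      sum(r[idx]) - na * (na + 1) / 2)
    U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    p_ref <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
    expect_equal(mw$p_value, p_ref)
    expect_equal(mw$U, unname(suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE))$statistic))
  }
  # large-sample branch is close to wilcox.test's corrected normal p
  set.seed(62)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  mw <- mann_whitney(a, b)
  expect_identical(mw$method, "normal")
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw$p_value, wt$p.value, tolerance = 1e-6)
  expect_error(mann_whitney(numeric(0), 1), "empty")
})
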