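# Locomotion-coupling statistics: episode segmentation, per-episode
# summaries, Q/L ratio, cross-correlation lag, paired runs and the
# paired-run ratio, and the Mann-Whitney U test.

#' Segment a speed trace into locomotion and quiescence episodes
#'
#' Locomotion episodes are maximal intervals where the (lightly smoothed)
#' speed exceeds `speed_thr`; gaps shorter than `merge_gap_s` are merged,
#' runs shorter than `min_run_s` discarded. The remainder is quiescence;
#' the episodes partition the recording and adjacent episodes never share
#' a label.
#'
#' @param speed data.frame `time_s`, `speed_cm_s` (uniformly sampled).
#' @param speed_thr threshold, cm/s (default 0.5).
#' @param min_run_s minimum run duration, s (default 1).
#' @param merge_gap_s sub-threshold gaps shorter than this are merged into
#'   the surrounding run, s (default 0.5).
#' @param smooth_s running-mean smoothing window, s (default 0.5).
#' @return data.frame `start_s`, `end_s`, `label`.
#' @export
segment_episodes <- function(speed, speed_thr = 0.5, min_run_s = 1,
                             merge_gap_s = 0.5, smooth_s = 0.5) {
  tt <- speed$time_s
  v <- speed$speed_cm_s
  n <- length(v)
  if (n < 2L) stop("speed trace too short")
  dt <- tt[2] - tt[1]
  w <- max(1L, round(smooth_s / dt))
  if (w > 1L) v <- stats::filter(v, rep(1 / w, w), sides = 2) |>
      (\(x) { x[is.na(x)] <- v[is.na(x)]; as.numeric(x) })()
  active <- v > speed_thr
  dur <- tt[n] + dt
  if (!any(active))
    return(data.frame(start_s = 0, end_s = dur, label = "quiescence"))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  iv <- data.frame(start = tt[starts], end = tt[ends] + dt, on = r$values)
  # merge short gaps into runs
  runs <- iv[iv$on, , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(runs))) {
    if (length(merged) &&
        runs$start[i] - merged[[length(merged)]][2] < merge_gap_s) {
      merged[[length(merged)]][2] <- runs$end[i]
    } else {
      merged[[length(merged) + 1L]] <- c(runs$start[i], runs$end[i])
    }
  }
  merged <- Filter(function(r) r[2] - r[1] >= min_run_s, merged)
  merged <- lapply(merged, function(r) c(max(0, r[1]), min(dur, r[2])))
  episodes_from_runs(merged, dur)
}

#' Per-episode means of a frame-level trace
#'
#' @param x numeric per-frame trace.
#' @param fs sampling rate of `x`, Hz.
#' @param episodes episode data.frame (`start_s`, `end_s`, `label`).
#' @return data.frame `episode`, `label`, `start_s`, `end_s`, `mean`;
#'   episodes shorter than one frame are skipped.
#' @export
episode_means <- function(x, fs, episodes) {
  tt <- (seq_along(x) - 1) / fs
  rows <- lapply(seq_len(nrow(episodes)), function(i) {
    sel <- tt >= episodes$start_s[i] & tt < episodes$end_s[i]
    if (!any(sel)) return(NULL)
    data.frame(episode = i, label = episodes$label[i],
               start_s = episodes$start_s[i], end_s = episodes$end_s[i],
               mean = mean(x[sel]))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Quiescence-to-locomotion activity ratio
#'
#' Mean of the trace over all quiescence time divided by its mean over all
#' locomotion time.
#'
#' @inheritParams episode_means
#' @return the Q/L ratio (`NA` if the locomotion mean is not positive or a
#'   state is absent).
#' @export
ql_ratio <- function(x, fs, episodes) {
  tt <- (seq_along(x) - 1) / fs
  in_l <- episode_indicator(tt, episodes, "locomotion")
  in_q <- episode_indicator(tt, episodes, "quiescence")
  if (!any(in_l) || !any(in_q)) return(NA_real_)
  ml <- mean(x[in_l])
  if (!is.finite(ml) || ml == 0) return(NA_real_)
  mean(x[in_q]) / ml
}

#' Cross-correlation of activity and speed
#'
#' Pearson-normalized cross-correlation between a dF/F (or active-area)
#' trace and the speed trace over lags in `[-max_lag_s, max_lag_s]`.
#' Positive lag means the activity follows the speed.
#'
#' @param x activity trace.
#' @param speed speed trace on the same time base as `x`.
#' @param fs common sampling rate, Hz.
#' @param max_lag_s lag range, seconds (default 15).
#' @param extremum `"max"` (default) returns the maximum coefficient;
#'   `"absmax"` the signed extremum of largest magnitude.
#' @return list with `r` (peak coefficient), `lag_s`, and the full
#'   `lags_s`/`r_all` profile.
#' @export
speed_dff_crosscorr <- function(x, speed, fs, max_lag_s = 15,
                                extremum = c("max", "absmax")) {
  extremum <- match.arg(extremum)
  if (stats::sd(x) == 0 || stats::sd(speed) == 0)
    stop("zero-variance input")
  n <- length(x)
  stopifnot(length(speed) == n)
  L <- min(n - 2L, round(max_lag_s * fs))
  lags <- -L:L
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- x[(1 + l):n]; b <- speed[1:(n - l)]
    } else {
      a <- x[1:(n + l)]; b <- speed[(1 - l):n]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  pick <- if (extremum == "max") which.max(r) else which.max(abs(r))
  list(r = r[pick], lag_s = lags[pick] / fs,
       lags_s = lags / fs, r_all = r)
}

#' Find closely timed pairs of running episodes
#'
#' Consecutive locomotion episodes separated by a quiescent gap strictly
#' shorter than `max_gap_s`; each episode joins at most one pair (greedy
#' left-to-right).
#'
#' @param episodes episode data.frame.
#' @param max_gap_s gap bound, seconds (default 30, strict).
#' @return data.frame `first_start_s`, `first_end_s`, `second_start_s`,
#'   `second_end_s`, `gap_s` (possibly empty).
#' @export
find_paired_runs <- function(episodes, max_gap_s = 30) {
  runs <- episodes[episodes$label == "locomotion", , drop = FALSE]
  out <- list()
  i <- 1L
  while (i < nrow(runs)) {
    gap <- runs$start_s[i + 1L] - runs$end_s[i]
    if (gap < max_gap_s) {
      out[[length(out) + 1L]] <-
        data.frame(first_start_s = runs$start_s[i],
                   first_end_s = runs$end_s[i],
                   second_start_s = runs$start_s[i + 1L],
                   second_end_s = runs$end_s[i + 1L],
                   gap_s = gap)
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(first_start_s = numeric(0), first_end_s = numeric(0),
                      second_start_s = numeric(0),
                      second_end_s = numeric(0), gap_s = numeric(0)))
  do.call(rbind, out)
}

#' Paired-run ratio (PRR)
#'
#' Ratio of the second to the first calcium response of a closely timed
#' run pair. The response window of each run extends from its onset to its
#' offset plus `post_s` seconds (accommodating the delayed astrocytic
#' response) but never into the next run's window. The default response
#' statistic is the peak of the trace in the window; the mean is reported
#' alongside.
#'
#' @param x activity trace (dF/F or active area).
#' @param fs sampling rate, Hz.
#' @param pair one row of [find_paired_runs()] output.
#' @param post_s window extension past the episode offset, s (default 10).
#' @return list with `prr_peak`, `prr_mean`, and the per-run responses;
#'   `NA` ratios when the first response is not positive.
#' @export
paired_run_ratio <- function(x, fs, pair, post_s = 10) {
  tt <- (seq_along(x) - 1) / fs
  w1 <- tt >= pair$first_start_s &
    tt < min(pair$first_end_s + post_s, pair$second_start_s)
  w2 <- tt >= pair$second_start_s & tt < pair$second_end_s + post_s
  if (!any(w1) || !any(w2)) stop("empty response window")
  p1 <- max(x[w1]); p2 <- max(x[w2])
  m1 <- mean(x[w1]); m2 <- mean(x[w2])
  list(prr_peak = if (p1 > 0) p2 / p1 else NA_real_,
       prr_mean = if (m1 > 0) m2 / m1 else NA_real_,
       response1_peak = p1, response2_peak = p2,
       response1_mean = m1, response2_mean = m2)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with an exact permutation branch for small samples
#' (`n_a + n_b <= exact_limit`, enumerating all assignments of the pooled
#' values, which handles ties exactly) and a tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @param exact_limit pooled-size bound for the exact branch (default 12).
#' @return list with `U` (statistic of sample `a`), `p_value` (two-sided),
#'   and `method`.
#' @export
mann_whitney <- function(a, b, exact_limit = 12L) {
  if (!length(a) || !length(b)) stop("empty sample")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na + nb <= exact_limit) {
    combs <- utils::combn(na + nb, na)
    Us <- apply(combs, 2, function(idx)
      sum(r[idx]) - na * (na + 1) / 2)
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    n <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal"
  }
  list(U = U, p_value = p, method = method)
}
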