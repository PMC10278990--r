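# Synthetic two-channel recordings with full ground truth.
#
# The generator emulates the phenomena of interest directly: alternating
# run/quiescence locomotion with occasional closely timed run pairs;
# astrocytes whose calcium transients start in the processes and reach the
# soma after a centripetal delay, with an amplified, oscillating somatic
# response and paired-run depletion; neuronal process-like units with
# near-zero-lag locomotion responses or high quiescent activity; and a
# Poisson-Gaussian camera with rigid frame-to-frame drift.

#' Generate a locomotion speed trace with ground-truth episodes
#'
#' Alternates quiescence and running episodes. Episode lengths are
#' exponential with the configured means; ordinary inter-run quiescence is
#' kept above 30 s so that only deliberately generated pairs qualify as
#' closely timed (< 30 s gap). Runs are trapezoidal speed bumps; speed is
#' exactly zero during quiescence.
#'
#' @param cfg a [scenario_config()].
#' @return list with `speed` (data.frame `time_s`, `speed_cm_s`),
#'   `episodes` (data.frame `start_s`, `end_s`, `label`), and `pairs`
#'   (data.frame of closely timed run pairs with their gaps).
#' @export
generate_speed_trace <- function(cfg) {
  validate_scenario_config(cfg)
  with_seed(cfg$seed * 7L + 1L, {
    dur <- cfg$duration_s
    fs <- cfg$fs_raw
    n <- round(dur * fs)
    tt <- (seq_len(n) - 1) / fs

    qmin <- 30.5                       # keeps unpaired runs > 30 s apart
    draw_quiet <- function() qmin +
      stats::rexp(1, 1 / max(cfg$mean_quiet_s - qmin, 1))
    draw_run <- function() min(max(stats::rexp(1, 1 / cfg$mean_run_s), 4),
                               3 * cfg$mean_run_s)

    runs <- list(); pairs <- list()
    cur <- max(10, min(cfg$mean_quiet_s, 20)) * stats::runif(1, 0.9, 1.1)
    while (cur < dur) {
      r1 <- draw_run()
      if (cur + 1 >= dur) break
      runs[[length(runs) + 1L]] <- c(cur, min(cur + r1, dur))
      cur <- cur + r1
      if (stats::runif(1) < cfg$paired_prob && cur < dur) {
        gap <- min(cfg$paired_gap_s * stats::runif(1, 0.85, 1.15), 29)
        r2 <- r1            # paired runs share the first run's duration
        s2 <- cur + gap
        if (s2 + 1 < dur) {
          runs[[length(runs) + 1L]] <- c(s2, min(s2 + r2, dur))
          pairs[[length(pairs) + 1L]] <-
            c(first = length(runs) - 1L, second = length(runs), gap = gap)
          cur <- s2 + r2
        }
      }
      cur <- cur + draw_quiet()
    }
    runs <- Filter(function(r) r[2] - r[1] >= 1, runs)

    speed <- numeric(n)
    for (r in runs) {
      ramp <- min(1.5, (r[2] - r[1]) / 4)
      in_run <- tt >= r[1] & tt < r[2]
      prof <- pmin(1, pmin((tt[in_run] - r[1]) / ramp,
                           (r[2] - tt[in_run]) / ramp))
      speed[in_run] <- cfg$run_speed_cms * pmax(prof, 0)
    }

    episodes <- episodes_from_runs(runs, dur)
    pair_df <- if (length(pairs)) {
      do.call(rbind, lapply(pairs, function(p) {
        data.frame(first_start_s = runs[[p["first"]]][1],
                   first_end_s = runs[[p["first"]]][2],
                   second_start_s = runs[[p["second"]]][1],
                   second_end_s = runs[[p["second"]]][2],
                   gap_s = unname(p["gap"]))
      }))
    } else {
      data.frame(first_start_s = numeric(0), first_end_s = numeric(0),
                 second_start_s = numeric(0), second_end_s = numeric(0),
                 gap_s = numeric(0))
    }
    list(speed = data.frame(time_s = tt, speed_cm_s = speed),
         episodes = episodes, pairs = pair_df)
  })
}

episodes_from_runs <- function(runs, dur) {
  if (!length(runs)) {
    return(data.frame(start_s = 0, end_s = dur, label = "quiescence"))
  }
  runs <- runs[order(vapply(runs, `[`, 0, 1))]
  out <- list(); cur <- 0
  for (r in runs) {
    if (r[1] > cur)
      out[[length(out) + 1L]] <- data.frame(start_s = cur, end_s = r[1],
                                            label = "quiescence")
    out[[length(out) + 1L]] <- data.frame(start_s = r[1], end_s = r[2],
                                          label = "locomotion")
    cur <- r[2]
  }
  if (cur < dur)
    out[[length(out) + 1L]] <- data.frame(start_s = cur, end_s = dur,
                                          label = "quiescence")
  do.call(rbind, out)
}

#' Generate a synthetic scene: astrocyte masks and neuronal footprints
#'
#' Astrocytes are star-shaped domains (a soma disk plus radial processes) on
#' a blank background; neuronal activity units are elongated curvilinear
#' footprints, emulating the process-dominated structures of cortical
#' layer 1.
#'
#' @param cfg a [scenario_config()].
#' @return list with `astro` (per-cell list of logical `domain`, `soma`,
#'   `processes` masks), `neuro_footprints` (list of `H x W` non-negative
#'   weight matrices with max 1), `stained` (logical mask of all labelled
#'   structure), `labels` (integer label image; soma label = domain
#'   label + 1000), and `structure` (non-negative brightness image).
#' @export
generate_scene <- function(cfg) {
  validate_scenario_config(cfg)
  with_seed(cfg$seed * 7L + 2L, {
    h <- cfg$fov[1]; w <- cfg$fov[2]
    R <- cfg$domain_radius_px; rs <- cfg$soma_radius_px
    struct <- matrix(0, h, w)
    labels <- matrix(0L, h, w)
    astro <- list()

    if (cfg$n_astro > 0) {
      cell <- 2 * R + 6
      if (h - R - 3 < R + 3 || w - R - 3 < R + 3)
        stop("placement error: field of view too small for domains of radius ",
             R, " px")
      gy <- seq(R + 3, h - R - 3, by = cell)
      gx <- seq(R + 3, w - R - 3, by = cell)
      if (length(gy) * length(gx) < cfg$n_astro)
        stop("placement error: field of view too small for ", cfg$n_astro,
             " astrocyte domains of radius ", R, " px")
      centers <- expand.grid(y = gy, x = gx)
      centers <- centers[sample(nrow(centers), cfg$n_astro), , drop = FALSE]
      for (i in seq_len(cfg$n_astro)) {
        cy <- centers$y[i] + stats::runif(1, -2, 2)
        cx <- centers$x[i] + stats::runif(1, -2, 2)
        m <- star_mask(h, w, cy, cx, R, rs,
                       n_arms = 8L, jitter = stats::runif(8, -0.15, 0.15))
        astro[[i]] <- m
        struct[m$domain] <- 1
        struct[m$soma] <- 1.2
        labels[m$domain] <- i
        labels[m$soma] <- i + 1000L
      }
      # domains must be pairwise disjoint by construction (grid placement)
      if (cfg$n_astro > 1) {
        tot <- Reduce(`+`, lapply(astro, function(m) m$domain + 0))
        if (max(tot) > 1) stop("placement error: overlapping domains")
      }
    }

    neuro <- list()
    if (cfg$n_neuro_units > 0) {
      for (u in seq_len(cfg$n_neuro_units)) {
        neuro[[u]] <- curvilinear_footprint(h, w)
        struct <- pmax(struct, 0.9 * neuro[[u]])
      }
    }

    # diffraction-limited optics: blur the emitted structure and the signal
    # weight fields with the PSF; ground-truth masks stay binary
    psf <- cfg$psf_sigma_px
    blur <- function(x) if (psf > 0)
      pmax(as.matrix(EBImage::gblur(x, sigma = psf)), 0) else x
    astro <- lapply(astro, function(m) {
      m$soma_w <- blur(m$soma + 0)
      m$proc_w <- blur(m$processes + 0)
      m
    })
    neuro <- lapply(neuro, function(fp) {
      w <- blur(fp)
      if (max(w) > 0) w / max(w) else w
    })
    struct <- blur(struct)
    stained <- struct > 0.2
    if (!any(stained)) stop("placement error: empty scene")
    list(astro = astro, neuro_footprints = neuro, stained = stained,
         labels = labels, structure = struct)
  })
}

# Soma disk + radial arms; returns logical domain/soma/processes masks.
star_mask <- function(h, w, cy, cx, R, rs, n_arms = 8L, jitter = 0) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- (yy - cy)^2 + (xx - cx)^2
  soma <- d2 <= rs^2
  domain <- soma
  ang <- 2 * pi * (seq_len(n_arms) - 1) / n_arms + jitter
  steps <- seq(rs - 1, R, by = 0.7)
  for (a in ang) {
    py <- cy + steps * sin(a)
    px <- cx + steps * cos(a)
    for (k in seq_along(steps)) {
      arm <- (yy - py[k])^2 + (xx - px[k])^2 <= 1.5^2
      domain <- domain | arm
    }
  }
  domain[c(1, h), ] <- domain[c(1, h), ] & FALSE  # stay off the border
  list(domain = domain, soma = soma, processes = domain & !soma)
}

# Smooth random-walk stroke with a Gaussian cross-section, max weight 1.
curvilinear_footprint <- function(h, w, len = 30L, width_sigma = 1.2) {
  margin <- 6
  y <- stats::runif(1, margin, h - margin)
  x <- stats::runif(1, margin, w - margin)
  th <- stats::runif(1, 0, 2 * pi)
  fp <- matrix(0, h, w)
  for (s in seq_len(len)) {
    th <- th + stats::rnorm(1, 0, 0.18)
    y <- min(max(y + sin(th), margin / 2), h - margin / 2)
    x <- min(max(x + cos(th), margin / 2), w - margin / 2)
    ys <- max(1, floor(y - 3)):min(h, ceiling(y + 3))
    xs <- max(1, floor(x - 3)):min(w, ceiling(x + 3))
    d2 <- outer((ys - y)^2, (xs - x)^2, `+`)
    fp[ys, xs] <- pmax(fp[ys, xs], exp(-d2 / (2 * width_sigma^2)))
  }
  fp / max(fp)
}

#' Simulate clean two-channel fluorescence from a scene and a speed trace
#'
#' Builds the noiseless movie pair. Astrocytic transients are
#' difference-of-exponentials; the process compartment responds first, the
#' soma follows after the configured centripetal delay with an amplified
#' (and optionally oscillating) response; the second run of a closely timed
#' pair is depleted by the factor `depletion_alpha`. Neuronal
#' locomotion-active units follow the speed profile convolved with a fast
#' kernel at the configured lag; quiescent-active units fire spontaneous
#' transients only outside runs. The red channel carries static morphology.
#'
#' @param cfg a [scenario_config()].
#' @param scene output of [generate_scene()].
#' @param speedinfo output of [generate_speed_trace()].
#' @return list with clean `green` and `red` [ca_movie()]s and `truth`
#'   (episodes, pairs, depletion factor, per-cell clean compartment traces
#'   and onset times, per-unit traces/types/footprints, scene masks).
#' @export
simulate_fluorescence <- function(cfg, scene, speedinfo) {
  validate_scenario_config(cfg)
  fs <- cfg$fs_raw
  tt <- speedinfo$speed$time_s
  n <- length(tt)
  h <- cfg$fov[1]; w <- cfg$fov[2]

  runs <- speedinfo$episodes[speedinfo$episodes$label == "locomotion", ,
                             drop = FALSE]
  second_of_pair <- rep(FALSE, nrow(runs))
  if (nrow(speedinfo$pairs)) {
    second_of_pair <- runs$start_s %in% speedinfo$pairs$second_start_s
  }

  kern <- function(rise, decay) {
    kt <- seq(0, 8 * decay, by = 1 / fs)
    k <- exp(-kt / decay) - exp(-kt / rise)
    k / max(k)
  }
  add_at <- function(trace, onset_s, amp, k) {
    i0 <- round(onset_s * fs) + 1L
    if (i0 > n) return(trace)
    idx <- i0:min(n, i0 + length(k) - 1L)
    trace[idx] <- trace[idx] + amp * k[seq_along(idx)]
    trace
  }

  truth <- list(episodes = speedinfo$episodes, pairs = speedinfo$pairs,
                depletion_alpha = cfg$depletion_alpha)

  traces <- list(); masksP <- list()
  astro_truth <- list()
  if (length(scene$astro)) {
    ka <- kern(cfg$astro_rise_s, cfg$astro_decay_s)
    cell_amp <- with_seed(cfg$seed * 7L + 3L,
                          stats::runif(length(scene$astro), 0.9, 1.1))
    for (i in seq_along(scene$astro)) {
      p <- numeric(n); s <- numeric(n)
      onsets <- data.frame(run_start_s = numeric(0), proc_onset_s = numeric(0),
                           soma_onset_s = numeric(0))
      if (nrow(runs)) for (r in seq_len(nrow(runs))) {
        # brief runs evoke sub-maximal astrocytic responses: amplitude
        # saturates with run duration (full size from ~10 s runs)
        dur_scale <- min(1, (runs$end_s[r] - runs$start_s[r]) / 10)
        a <- cfg$astro_peak_dff * cell_amp[i] * dur_scale *
          if (second_of_pair[r]) cfg$depletion_alpha else 1
        t_proc <- runs$start_s[r] + cfg$astro_onset_lag_s
        t_soma <- t_proc + cfg$soma_delay_s
        p <- add_at(p, t_proc, a, ka)
        s_add <- numeric(n)
        s_add <- add_at(s_add, t_soma, cfg$soma_amp * a, ka)
        if (cfg$osc_amp > 0) {
          on <- s_add > 0.15 * max(s_add, .Machine$double.eps)
          s_add[on] <- s_add[on] *
            (1 + cfg$osc_amp * sin(2 * pi * cfg$osc_freq_hz * (tt[on] - t_soma)))
        }
        s <- s + s_add
        onsets <- rbind(onsets, data.frame(run_start_s = runs$start_s[r],
                                           proc_onset_s = t_proc,
                                           soma_onset_s = t_soma))
      }
      cell <- scene$astro[[i]]
      traces[[length(traces) + 1L]] <- p
      masksP[[length(masksP) + 1L]] <- as.numeric(
        if (is.null(cell$proc_w)) cell$processes + 0 else cell$proc_w)
      traces[[length(traces) + 1L]] <- s
      masksP[[length(masksP) + 1L]] <- as.numeric(
        if (is.null(cell$soma_w)) cell$soma + 0 else cell$soma_w)
      astro_truth[[i]] <- list(proc_trace = p, soma_trace = s, onsets = onsets)
    }
  }

  unit_truth <- list()
  if (length(scene$neuro_footprints)) {
    kn <- kern(cfg$neuro_rise_s, cfg$neuro_decay_s)
    nu <- length(scene$neuro_footprints)
    n_q <- round(cfg$quiescent_frac * nu)
    types <- with_seed(cfg$seed * 7L + 4L,
                       sample(c(rep("quiescent_active", n_q),
                                rep("locomotion_active", nu - n_q))))
    drive <- speedinfo$speed$speed_cm_s
    drive <- if (max(drive) > 0) drive / max(drive) else drive
    # per-run drive segments, so units can respond with run-to-run gain
    # variability (synchronous but not collinear dynamics)
    run_resp <- lapply(seq_len(nrow(runs)), function(r) {
      dr <- drive
      keep <- tt >= runs$start_s[r] & tt < runs$end_s[r] + 2
      dr[!keep] <- 0
      x <- stats::convolve(dr, rev(kn), type = "open")[seq_len(n)]
      if (max(x) > 0) x / max(x) else x
    })
    shift_lag <- function(x) {
      if (cfg$neuro_lag_s == 0) return(x)
      sh <- round(cfg$neuro_lag_s * fs)
      x <- c(rep(0, max(sh, 0)), utils::head(x, n - abs(sh)))
      utils::head(c(x, rep(0, abs(sh))), n)
    }
    # run-to-run participation: units join most runs with variable gain and
    # occasionally sit one out, as cortical ensembles do
    run_gain <- with_seed(cfg$seed * 7L + 7L, {
      nr <- max(nrow(runs), 1)
      g <- matrix(stats::runif(nu * nr, 0.3, 1.7), nu)
      drop <- matrix(stats::runif(nu * nr) < 0.3, nu)
      # never drop every run for a unit
      for (u in seq_len(nu)) if (all(drop[u, ])) drop[u, sample(nr, 1)] <- FALSE
      g[drop] <- 0
      g
    })
    q_int <- speedinfo$episodes[speedinfo$episodes$label == "quiescence", ,
                                drop = FALSE]
    ev_all <- with_seed(cfg$seed * 7L + 5L, {
      lapply(seq_len(nu), function(u) {
        if (types[u] != "quiescent_active") return(numeric(0))
        unlist(lapply(seq_len(nrow(q_int)), function(q) {
          len <- q_int$end_s[q] - q_int$start_s[q]
          k <- stats::rpois(1, cfg$q_event_rate_hz * len)
          if (k == 0) return(numeric(0))
          stats::runif(k, q_int$start_s[q], q_int$end_s[q])
        }))
      })
    })
    for (u in seq_len(nu)) {
      cu <- if (types[u] == "locomotion_active") {
        x <- numeric(n)
        for (r in seq_along(run_resp))
          x <- x + run_gain[u, r] * run_resp[[r]]
        shift_lag(cfg$neuro_peak_dff * x)
      } else {
        tr <- numeric(n)
        for (te in ev_all[[u]]) tr <- add_at(tr, te, cfg$neuro_peak_dff, kn)
        tr
      }
      traces[[length(traces) + 1L]] <- cu
      masksP[[length(masksP) + 1L]] <- as.numeric(scene$neuro_footprints[[u]])
      unit_truth[[u]] <- list(trace = cu, type = types[u],
                              footprint = scene$neuro_footprints[[u]])
    }
  }

  bg <- 5; amp_g <- 100; amp_r <- 80
  Bg <- bg + amp_g * scene$structure
  Br <- bg + amp_r * scene$structure

  green_mat <- matrix(Bg, h * w, n)                 # recycles column-wise
  if (length(traces)) {
    M <- do.call(cbind, masksP)                     # pixels x components
    C <- do.call(rbind, lapply(traces, rbind))      # components x time
    green_mat <- green_mat * (1 + M %*% C)
  }
  green <- ca_movie(array(green_mat, c(h, w, n)), fs, "green")
  red <- ca_movie(array(rep(Br, n), c(h, w, n)), fs, "red")

  truth$astro <- astro_truth
  truth$units <- unit_truth
  truth$scene <- scene
  list(green = green, red = red, truth = truth)
}

#' Apply the camera model: rigid drift plus Poisson-Gaussian noise
#'
#' Both channels of a frame receive the same integer rigid shift (a random
#' walk clipped to the configured maximum, starting at zero); intensities
#' then pass through a Poisson photon branch with the configured gain and
#' additive Gaussian read noise, and are rounded to non-negative integer
#' counts. A flat region of mean m therefore has variance close to
#' `gain * m + read_sd^2`. `gain = 0` and `read_sd = 0` disable the
#' respective branches.
#'
#' @param sim output of [simulate_fluorescence()] (clean movie pair).
#' @param cfg the same [scenario_config()].
#' @return list with noisy `green` and `red` movies and `shifts`
#'   (data.frame `frame`, `dy_px`, `dx_px`).
#' @export
apply_camera <- function(sim, cfg) {
  validate_scenario_config(cfg)
  n <- n_frames(sim$green)
  with_seed(cfg$seed * 7L + 6L, {
    mx <- cfg$max_shift_px
    if (mx > 0) {
      dy <- cumsum(c(0L, sample(-1:1, n - 1, replace = TRUE)))
      dx <- cumsum(c(0L, sample(-1:1, n - 1, replace = TRUE)))
      dy <- pmin(pmax(dy, -mx), mx)
      dx <- pmin(pmax(dx, -mx), mx)
    } else {
      dy <- dx <- rep(0L, n)
    }
    noisify <- function(m) {
      fr <- m$frames
      for (t in seq_len(n)) {
        if (dy[t] != 0 || dx[t] != 0)
          fr[, , t] <- translate_int(fr[, , t], dy[t], dx[t])
      }
      if (cfg$gain > 0)
        fr <- array(cfg$gain * stats::rpois(length(fr), fr / cfg$gain),
                    dim(fr))
      if (cfg$read_sd > 0)
        fr <- fr + stats::rnorm(length(fr), 0, cfg$read_sd)
      fr <- pmax(round(fr), 0)
      out <- m; out$frames <- fr; out
    }
    list(green = noisify(sim$green), red = noisify(sim$red),
         shifts = data.frame(frame = seq_len(n) - 1L, dy_px = dy, dx_px = dx))
  })
}

#' Simulate a complete synthetic recording
#'
#' Convenience wrapper chaining [generate_speed_trace()], [generate_scene()],
#' [simulate_fluorescence()] and [apply_camera()].
#'
#' @param cfg a [scenario_config()].
#' @return list with `speed`, `clean` (noiseless movie pair), `noisy`
#'   (camera output + shifts) and `truth`.
#' @export
simulate_recording <- function(cfg) {
  sp <- generate_speed_trace(cfg)
  sc <- generate_scene(cfg)
  sim <- simulate_fluorescence(cfg, sc, sp)
  cam <- apply_camera(sim, cfg)
  sim$truth$shifts <- cam$shifts
  list(speed = sp, clean = list(green = sim$green, red = sim$red),
       noisy = cam, truth = sim$truth)
}
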