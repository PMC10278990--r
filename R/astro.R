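# Single-astrocyte analysis: soma/process compartment timecourses, onset
# latency, somatic oscillation band power, domain size, and the
# latency-vs-size regression.

#' Compartment dF/F timecourses
#'
#' Per-frame mean dF/F over the soma mask and over the processes mask
#' (domain minus soma).
#'
#' @param d a `dff_movie`.
#' @param cell list with logical `soma` and `processes` masks (e.g. one
#'   element of a synthetic scene, or parsed ROI masks).
#' @return list with numeric vectors `soma` and `processes` (%, per frame)
#'   and `fs`.
#' @export
compartment_traces <- function(d, cell) {
  stopifnot(inherits(d, "dff_movie"))
  dd <- dim(d$dff)
  X <- matrix(d$dff, dd[1] * dd[2], dd[3])
  soma_idx <- which(as.logical(cell$soma))
  proc_idx <- which(as.logical(cell$processes))
  if (!length(soma_idx) || !length(proc_idx))
    stop("empty compartment mask")
  list(soma = colMeans(X[soma_idx, , drop = FALSE], na.rm = TRUE),
       processes = colMeans(X[proc_idx, , drop = FALSE], na.rm = TRUE),
       fs = d$fs)
}

#' Normalize a trace to its peak
#'
#' @param trace numeric vector with a positive maximum.
#' @return the trace divided by its maximum (peak value 1).
#' @export
normalize_to_peak <- function(trace) {
  pk <- max(trace)
  if (!is.finite(pk) || pk <= 0) stop("trace peak must be positive")
  trace / pk
}

#' Soma-process onset latency
#'
#' The latency is the time at which the normalized soma trace first crosses
#' `fraction` of its maximum minus the time the normalized process trace
#' does, in seconds; positive latency means the processes lead (centripetal
#' propagation). Crossing times are linearly interpolated between samples.
#' If either trace never crosses, the latency is `NA` (excluded from
#' summaries).
#'
#' @param soma,processes peak-normalized traces (see [normalize_to_peak()]).
#' @param fs sampling rate, Hz.
#' @param fraction onset fraction of the maximum (default 0.15).
#' @param window optional integer index range (e.g. around a locomotion
#'   episode) restricting the search.
#' @return latency in seconds, or `NA`.
#' @export
onset_latency <- function(soma, processes, fs, fraction = 0.15,
                          window = NULL) {
  if (!is.null(window)) {
    soma <- soma[window]; processes <- processes[window]
  }
  ts <- first_crossing(soma, fraction)
  tp <- first_crossing(processes, fraction)
  if (is.na(ts) || is.na(tp)) return(NA_real_)
  (ts - tp) / fs
}

# first up-crossing index (fractional, 0-based) of level `f`
first_crossing <- function(x, f) {
  above <- x >= f
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1L) return(0)
  (i - 2) + (f - x[i - 1]) / (x[i] - x[i - 1])
}

#' Morlet continuous wavelet transform power
#'
#' Computes the CWT of a demeaned trace with a Morlet mother wavelet
#' (center frequency parameter 6) at the requested frequencies, via the
#' FFT of the analytic wavelet filter.
#'
#' @param trace numeric vector.
#' @param fs sampling rate, Hz.
#' @param freqs frequencies to evaluate, Hz.
#' @param omega0 Morlet center frequency parameter (default 6).
#' @return matrix `length(freqs) x length(trace)` of wavelet power.
#' @export
morlet_cwt_power <- function(trace, fs, freqs, omega0 = 6) {
  x <- trace - mean(trace)
  n <- length(x)
  dt <- 1 / fs
  fx <- stats::fft(x)
  wk <- 2 * pi * c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * dt)
  fourier_factor <- (4 * pi) / (omega0 + sqrt(2 + omega0^2))
  out <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    scale <- 1 / (fourier_factor * freqs[i])
    psi <- numeric(n)
    pos <- wk > 0
    psi[pos] <- pi^(-1 / 4) * sqrt(2 * pi * scale / dt) *
      exp(-(scale * wk[pos] - omega0)^2 / 2)
    W <- stats::fft(fx * psi, inverse = TRUE) / n
    out[i, ] <- Mod(W)^2
  }
  out
}

#' Wavelet band power over the active interval
#'
#' Mean Morlet wavelet power of the trace over the times when it exceeds
#' `active_fraction` of its peak and over the frequency band (default
#' 0.1-0.3 Hz, the somatic oscillation band).
#'
#' @param trace dF/F trace (need not be normalized).
#' @param fs sampling rate, Hz; must exceed twice the band's upper edge.
#' @param band frequency band `c(lo, hi)` in Hz.
#' @param active_fraction peak fraction defining the active interval.
#' @param n_freqs number of frequencies spanning the band.
#' @return mean band power (a.u.), or `NA` if the active interval is empty.
#' @export
wavelet_band_power <- function(trace, fs, band = c(0.1, 0.3),
                               active_fraction = 0.15, n_freqs = 9L) {
  if (fs <= 2 * band[2]) stop("sampling rate too low for the band")
  pk <- max(trace)
  active <- trace > active_fraction * pk
  if (!any(active)) return(NA_real_)
  freqs <- seq(band[1], band[2], length.out = n_freqs)
  P <- morlet_cwt_power(trace, fs, freqs)
  mean(P[, active])
}

#' Maximum Feret diameter of a mask
#'
#' Largest pairwise distance between pixel centers of the mask, scaled by
#' the pixel size. Computed on the convex hull of the mask pixels.
#'
#' @param mask logical matrix.
#' @param pixel_size length per pixel (default 1, i.e. px units).
#' @return maximum Feret diameter.
#' @export
feret_diameter <- function(mask, pixel_size = 1) {
  pts <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pts) == 0L) stop("empty mask")
  if (nrow(pts) == 1L) return(0)
  hull <- tryCatch(grDevices::chull(pts[, 2], pts[, 1]),
                   error = function(e) seq_len(nrow(pts)))
  p <- pts[hull, , drop = FALSE]
  d2max <- 0
  for (i in seq_len(nrow(p) - 1L)) {
    d2 <- (p[(i + 1):nrow(p), 1] - p[i, 1])^2 +
      (p[(i + 1):nrow(p), 2] - p[i, 2])^2
    d2max <- max(d2max, d2)
  }
  sqrt(d2max) * pixel_size
}

#' Latency vs astrocyte size regression
#'
#' Ordinary least-squares regression of soma-process latency on maximum
#' Feret diameter, reporting the slope, R-squared and the two-sided p-value
#' of the slope.
#'
#' @param latencies,diameters paired numeric vectors; pairs with missing
#'   values are dropped.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
latency_size_regression <- function(latencies, diameters) {
  ok <- is.finite(latencies) & is.finite(diameters)
  x <- diameters[ok]; y <- latencies[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  if (stats::var(x) == 0) stop("diameters have zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(x))
}

#' Per-cell astrocyte summary table
#'
#' Runs the compartment analysis for each cell of a scene over a dF/F
#' movie: peak dF/F per compartment, onset latency, wavelet band power and
#' Feret diameter.
#'
#' @param d a `dff_movie`.
#' @param cells list of cells (each with `domain`, `soma`, `processes`).
#' @param pixel_size_um pixel size for the Feret diameter (default 1 px).
#' @param window optional index window for the latency search.
#' @return data.frame, one row per cell.
#' @export
astro_cell_table <- function(d, cells, pixel_size_um = 1, window = NULL) {
  rows <- lapply(seq_along(cells), function(i) {
    tr <- compartment_traces(d, cells[[i]])
    sn <- normalize_to_peak(tr$soma)
    pn <- normalize_to_peak(tr$processes)
    data.frame(cell_id = i,
               latency_s = onset_latency(sn, pn, tr$fs, window = window),
               soma_peak_pct = max(tr$soma),
               proc_peak_pct = max(tr$processes),
               soma_power = wavelet_band_power(tr$soma, tr$fs),
               proc_power = wavelet_band_power(tr$processes, tr$fs),
               feret = feret_diameter(cells[[i]]$domain, pixel_size_um))
  })
  do.call(rbind, rows)
}
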