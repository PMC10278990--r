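# Pixel-wise dF/F with a lower-envelope baseline, mode bias correction,
# and active-area event detection.

#' Lower-envelope fluorescence baseline
#'
#' Estimates the slowly varying baseline F0 of each pixel (or trace) as a
#' running local minimum smoothed by a temporal Gaussian filter with
#' `sigma_t` seconds. The local-minimum window defaults to `sigma_t` as
#' well; both are exposed because only the smoothing sigma is a fixed
#' methodological constant (15 s) while the minimum window is an
#' implementation choice.
#'
#' @param F a [ca_movie()], a pixels-by-time matrix, or a numeric vector.
#' @param fs sampling rate in Hz (taken from the movie if omitted).
#' @param sigma_t Gaussian smoothing sigma, seconds (default 15).
#' @param window_s running-minimum window, seconds (default `sigma_t`).
#' @return baseline of the same shape as the input.
#' @export
baseline_envelope <- function(F, fs = NULL, sigma_t = 15, window_s = sigma_t) {
  if (inherits(F, "ca_movie")) {
    if (is.null(fs)) fs <- F$fs
    X <- as_pixel_matrix(F)
    B <- baseline_envelope(X, fs, sigma_t, window_s)
    return(movie_from_pixel_matrix(B, F))
  }
  vec <- is.null(dim(F))
  X <- if (vec) matrix(F, 1) else F
  if (is.null(fs)) stop("`fs` is required for matrix/vector input")
  if (ncol(X) < 3L) stop("need at least 3 time points")
  w <- max(3L, round(window_s * fs))
  B <- running_min_time(X, w)
  B <- gauss_smooth_time(B, sigma_t * fs)
  if (vec) as.numeric(B) else B
}

#' Mode-based baseline bias correction
#'
#' The running-minimum envelope is negatively biased. This shifts the
#' baseline of each pixel by the constant that brings the mode of the
#' residuals F - F0 to zero, on the rationale that the most frequent
#' fluctuations are noise while true calcium events are sparse. The mode is
#' estimated from a histogram whose bin width is half the robust (MAD-based)
#' residual SD.
#'
#' @param F movie/matrix/vector as in [baseline_envelope()].
#' @param F0 baseline of the same shape.
#' @return the corrected baseline F0'.
#' @export
mode_bias_correct <- function(F, F0) {
  if (inherits(F, "ca_movie")) {
    B <- mode_bias_correct(as_pixel_matrix(F), as_pixel_matrix(F0))
    return(movie_from_pixel_matrix(B, F))
  }
  vec <- is.null(dim(F))
  X <- if (vec) matrix(F, 1) else F
  B <- if (vec) matrix(F0, 1) else F0
  R <- X - B
  off <- apply(R, 1, residual_mode)
  B <- B + off
  if (vec) as.numeric(B) else B
}

residual_mode <- function(r) {
  s <- stats::mad(r)
  rng <- range(r)
  if (s == 0 || rng[2] == rng[1]) return(r[1])  # degenerate residuals
  # bin width: half the robust SD, but never more than ~4096 bins across
  # the residual range (tiny MADs on very smooth pixels would overflow)
  bw <- max(s / 2, (rng[2] - rng[1]) / 4096)
  br <- floor(r / bw)
  b0 <- min(br)
  modal <- which.max(tabulate(br - b0 + 1L)) + b0 - 1L
  (modal + 0.5) * bw
}

#' Relative fluorescence change dF/F
#'
#' Computes `(F - F0) / F0 * 100` (percent) element-wise. Pixels where the
#' baseline is non-positive (or outside the stained mask, if given) are set
#' to `NA` with a warning count.
#'
#' @param F movie/matrix/vector of fluorescence.
#' @param F0 bias-corrected baseline of the same shape.
#' @param stained_mask optional logical `H x W` mask (movies only).
#' @return for movies, a `dff_movie` list (`dff` array in %, `fs`,
#'   `stained_mask`); otherwise an object of the input shape, in %.
#' @export
compute_dff <- function(F, F0, stained_mask = NULL) {
  if (inherits(F, "ca_movie")) {
    d <- dim(F$frames)
    X <- as_pixel_matrix(F)
    B <- as_pixel_matrix(F0)
    dff <- dff_core(X, B)
    if (!is.null(stained_mask)) dff[!as.logical(stained_mask), ] <- NA_real_
    return(structure(list(dff = array(dff, d), fs = F$fs,
                          stained_mask = if (is.null(stained_mask))
                            matrix(TRUE, d[1], d[2]) else stained_mask),
                     class = "dff_movie"))
  }
  vec <- is.null(dim(F))
  out <- dff_core(if (vec) matrix(F, 1) else F,
                  if (vec) matrix(F0, 1) else F0)
  if (vec) as.numeric(out) else out
}

dff_core <- function(X, B) {
  bad <- rowSums(B <= 0) > 0
  if (any(bad))
    warning(sum(bad), " pixel(s) with non-positive baseline excluded")
  out <- (X - B) / B * 100
  out[bad, ] <- NA_real_
  out
}

#' dF/F pipeline for a movie
#'
#' Chains [baseline_envelope()], [mode_bias_correct()] and [compute_dff()].
#'
#' @inheritParams baseline_envelope
#' @param stained_mask optional logical mask; defaults to
#'   [stained_mask()] of the mean image.
#' @return a `dff_movie`.
#' @export
dff_movie_pipeline <- function(F, sigma_t = 15, window_s = sigma_t,
                               stained_mask = NULL) {
  if (is.null(stained_mask)) {
    mean_img <- apply(F$frames, c(1, 2), mean)
    stained_mask <- caflux::stained_mask(mean_img)
  }
  F0 <- baseline_envelope(F, sigma_t = sigma_t, window_s = window_s)
  F0 <- mode_bias_correct(F, F0)
  compute_dff(F, F0, stained_mask)
}

#' Stained-area mask from a mean image
#'
#' Thresholds the time-averaged image at a fixed fraction of its dynamic
#' range above the background level (the image median, since unlabelled
#' tissue dominates the field of view). The rule is invariant to a global
#' intensity scale and deliberately inclusive of dim process edges, which
#' a between-class threshold such as Otsu's would cut off.
#'
#' @param mean_img finite numeric matrix (time-averaged frame).
#' @param frac fraction of the background-to-bright range (default 0.2);
#'   bright level is the 99th intensity percentile.
#' @return logical mask of the stained area.
#' @export
stained_mask <- function(mean_img, frac = 0.2) {
  if (any(!is.finite(mean_img))) stop("mean image must be finite")
  bg <- stats::median(mean_img)
  hi <- stats::quantile(mean_img, 0.99, names = FALSE)
  if (hi <= bg || stats::sd(mean_img) == 0)
    stop("cannot estimate a stained mask from a featureless image")
  mask <- mean_img > bg + frac * (hi - bg)
  if (!any(mask)) stop("stained mask is empty")
  mask
}

#' Detect active segments in a dF/F movie
#'
#' Per frame, 8-connected clusters of suprathreshold stained pixels
#' (`dff >= thr`) strictly larger than `min_pixels` are kept; clusters are
#' linked across consecutive frames by spatial overlap (>= 1 shared pixel),
#' and a linked chain is retained as an active segment only if it spans at
#' least `min_frames` consecutive frames.
#'
#' @param d a `dff_movie`.
#' @param thr dF/F threshold in percent (default 15).
#' @param min_pixels cluster size threshold; clusters must exceed it
#'   (strictly more than 16 pixels by default).
#' @param min_frames minimum chain length in frames (default 3).
#' @return list of class `active_segments`: `labels` (`H x W x T` integer
#'   array of segment ids), `segments` (data.frame `segment`, `frame`,
#'   `n_pixels`), `stained_mask`, `fs`.
#' @export
detect_active_segments <- function(d, thr = 15, min_pixels = 16L,
                                   min_frames = 3L) {
  stopifnot(inherits(d, "dff_movie"))
  dd <- dim(d$dff)
  Tn <- dd[3]
  stained <- as.logical(d$stained_mask)
  clusters <- vector("list", Tn)   # per frame: list of pixel-index vectors
  for (t in seq_len(Tn)) {
    fr <- d$dff[, , t]
    bin <- !is.na(fr) & fr >= thr
    bin[!stained] <- FALSE
    if (!any(bin)) { clusters[[t]] <- list(); next }
    lab <- label_components8(bin)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes > min_pixels)
    clusters[[t]] <- lapply(keep, function(k) which(lab == k))
  }
  # link clusters across consecutive frames by >= 1 shared pixel
  ids <- list(); node <- 0L
  for (t in seq_len(Tn)) {
    ids[[t]] <- if (length(clusters[[t]]))
      node + seq_along(clusters[[t]]) else integer(0)
    node <- node + length(clusters[[t]])
  }
  if (node == 0L) {
    return(structure(list(labels = array(0L, dd),
                          segments = data.frame(segment = integer(0),
                                                frame = integer(0),
                                                n_pixels = integer(0)),
                          stained_mask = d$stained_mask, fs = d$fs),
                     class = "active_segments"))
  }
  edges <- integer(0)
  for (t in seq_len(Tn - 1L)) {
    for (i in seq_along(clusters[[t]])) {
      for (j in seq_along(clusters[[t + 1L]])) {
        if (length(intersect(clusters[[t]][[i]], clusters[[t + 1L]][[j]])))
          edges <- c(edges, ids[[t]][i], ids[[t + 1L]][j])
      }
    }
  }
  g <- igraph::make_graph(edges, n = node, directed = FALSE)
  comp <- igraph::components(g)$membership
  # frame of each node
  frame_of <- integer(node)
  for (t in seq_len(Tn)) frame_of[ids[[t]]] <- t
  span <- tapply(frame_of, comp, function(f) length(unique(f)))
  keep_comp <- as.integer(names(span)[span >= min_frames])

  labels <- array(0L, dd)
  rows <- list()
  seg_id <- stats::setNames(seq_along(keep_comp), keep_comp)
  for (t in seq_len(Tn)) {
    for (i in seq_along(clusters[[t]])) {
      cid <- comp[ids[[t]][i]]
      if (cid %in% keep_comp) {
        sid <- seg_id[[as.character(cid)]]
        fr <- labels[, , t]
        fr[clusters[[t]][[i]]] <- sid
        labels[, , t] <- fr
        rows[[length(rows) + 1L]] <-
          data.frame(segment = sid, frame = t - 1L,
                     n_pixels = length(clusters[[t]][[i]]))
      }
    }
  }
  segments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(segment = integer(0), frame = integer(0),
               n_pixels = integer(0))
  structure(list(labels = labels, segments = segments,
                 stained_mask = d$stained_mask, fs = d$fs),
            class = "active_segments")
}

#' Active-area timecourse
#'
#' Per frame, the pixel count of retained active segments as a percentage
#' of the stained area.
#'
#' @param segs an `active_segments` object.
#' @param stained_mask optional override of the stained mask.
#' @return data.frame `time_s`, `active_area_pct` (in [0, 100]).
#' @export
active_area_trace <- function(segs, stained_mask = NULL) {
  stopifnot(inherits(segs, "active_segments"))
  mask <- if (is.null(stained_mask)) segs$stained_mask else stained_mask
  n_stained <- sum(as.logical(mask))
  if (n_stained == 0) stop("stained mask is empty")
  Tn <- dim(segs$labels)[3]
  act <- vapply(seq_len(Tn), function(t) sum(segs$labels[, , t] > 0), 0L)
  data.frame(time_s = (seq_len(Tn) - 1) / segs$fs,
             active_area_pct = 100 * act / n_stained)
}

#' Frame-mean dF/F over the stained area
#'
#' @param d a `dff_movie`.
#' @return data.frame `time_s`, `mean_dff_pct`.
#' @export
frame_mean_dff <- function(d) {
  stopifnot(inherits(d, "dff_movie"))
  dd <- dim(d$dff)
  X <- matrix(d$dff, dd[1] * dd[2], dd[3])
  X <- X[as.logical(d$stained_mask), , drop = FALSE]
  data.frame(time_s = (seq_len(dd[3]) - 1) / d$fs,
             mean_dff_pct = colMeans(X, na.rm = TRUE))
}
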