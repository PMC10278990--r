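# Preprocessing: temporal binning, rigid motion correction driven by the
# autofluorescence channel, and Anscombe/patch-SVD denoising.

#' Temporal binning by summation
#'
#' Sums intensities in non-overlapping batches of `batch` frames; trailing
#' remainder frames are discarded. The output frame rate is `fs / batch`.
#' Binning by summation conserves total intensity over the retained frames
#' and raises SNR before motion correction and denoising.
#'
#' @param m a [ca_movie()].
#' @param batch frames per bin (default 5, turning 30 Hz into 6 Hz).
#' @return a binned [ca_movie()].
#' @export
temporal_bin <- function(m, batch = 5L) {
  batch <- as.integer(batch)
  if (batch < 1L) stop("`batch` must be >= 1")
  Tn <- n_frames(m)
  if (batch > Tn) stop("`batch` exceeds the number of frames")
  if (batch == 1L) return(m)
  Tout <- Tn %/% batch
  d <- dim(m$frames)
  x <- array(m$frames[, , seq_len(Tout * batch)], c(d[1] * d[2], batch, Tout))
  acc <- x[, 1, ]
  for (j in 2:batch) acc <- acc + x[, j, ]
  out <- m
  out$frames <- array(acc, c(d[1], d[2], Tout))
  out$fs <- m$fs / batch
  out
}

#' Denoise the autofluorescence reference stack
#'
#' Approximates each frame by the leading spatial principal components of
#' the mean-centered stack, with each spatial component smoothed by a
#' Gaussian filter, yielding a stable morphology reference for shift
#' estimation.
#'
#' @param red a [ca_movie()] (red/autofluorescence channel).
#' @param n_components number of spatial principal components (default 50).
#' @param sigma_px Gaussian smoothing sigma for the spatial components,
#'   pixels (0 disables smoothing).
#' @return a denoised [ca_movie()] of the same shape.
#' @export
denoise_reference <- function(red, n_components = 50L, sigma_px = 1) {
  Tn <- n_frames(red)
  k <- as.integer(n_components)
  if (Tn <= k) {
    k <- max(1L, Tn - 1L)
    warning("rank reduced to ", k, " (stack has only ", Tn, " frames)")
  }
  d <- dim(red$frames)
  X <- t(as_pixel_matrix(red))              # T x P
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- trunc_svd(Xc, k)
  V <- sv$v                                 # P x k spatial components
  if (sigma_px > 0) {
    # the mean image is the zeroth spatial component and is smoothed too,
    # so every reconstructed frame is a consistently blurred image
    mu <- as.numeric(EBImage::gblur(matrix(mu, d[1], d[2]),
                                    sigma = sigma_px))
    for (j in seq_len(ncol(V))) {
      V[, j] <- as.numeric(EBImage::gblur(matrix(V[, j], d[1], d[2]),
                                          sigma = sigma_px))
    }
  }
  coef <- sv$u %*% diag(sv$d, nrow = k)     # T x k
  Xhat <- coef %*% t(V)
  Xhat <- sweep(Xhat, 2, mu, `+`)
  out <- red
  out$frames <- array(t(Xhat), d)
  out$frames[out$frames < 0] <- 0
  out
}

#' Estimate per-frame rigid shifts by phase correlation
#'
#' Each frame is phase-correlated against the per-pixel median template of
#' the stack; the integer peak of the correlation surface gives the frame's
#' displacement. The cross-power spectrum is regularized
#' (`R / (|R| + eps * mean|R|)`) so the whitening does not amplify noise,
#' and a second pass re-estimates residual shifts against the template of
#' the realigned stack. The series is re-anchored so that the first frame
#' (the reference frame) has shift (0, 0).
#'
#' @param ref a [ca_movie()], typically the denoised red channel.
#' @param eps relative spectral regularization (default 0.5).
#' @param n_passes alignment passes (default 2).
#' @return data.frame `frame` (0-based), `dy_px`, `dx_px`.
#' @export
estimate_shifts <- function(ref, eps = 0.5, n_passes = 2L) {
  d <- dim(ref$frames)
  Tn <- d[3]
  if (stats::sd(ref$frames) == 0) {
    warning("featureless reference; returning zero shifts")
    return(data.frame(frame = seq_len(Tn) - 1L,
                      dy_px = rep(0L, Tn), dx_px = rep(0L, Tn)))
  }
  dy <- integer(Tn); dx <- integer(Tn)
  fr <- ref$frames
  for (pass in seq_len(max(1L, n_passes))) {
    P <- matrix(fr, d[1] * d[2], Tn)
    template <- matrix(apply(P, 1, stats::median), d[1], d[2])
    Ft <- stats::fft(template - mean(template))
    moved <- FALSE
    for (t in seq_len(Tn)) {
      f <- fr[, , t]
      R <- stats::fft(f - mean(f)) * Conj(Ft)
      R <- R / (Mod(R) + eps * mean(Mod(R)))
      r <- Re(stats::fft(R, inverse = TRUE))
      pk <- which.max(r)
      py <- (pk - 1) %% d[1]
      px <- (pk - 1) %/% d[1]
      if (py > d[1] / 2) py <- py - d[1]
      if (px > d[2] / 2) px <- px - d[2]
      if (py != 0 || px != 0) {
        dy[t] <- dy[t] + as.integer(py); dx[t] <- dx[t] + as.integer(px)
        fr[, , t] <- translate_int(ref$frames[, , t], -dy[t], -dx[t])
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  data.frame(frame = seq_len(Tn) - 1L,
             dy_px = as.integer(dy - dy[1]), dx_px = as.integer(dx - dx[1]))
}

#' Apply a shift series to a movie
#'
#' Translates each frame by the negated shift (undoing the estimated
#' displacement); out-of-frame pixels are filled with the replicated border
#' value, which avoids introducing zeros that would bias dF/F.
#'
#' @param m a [ca_movie()] (typically the green channel).
#' @param shifts data.frame from [estimate_shifts()] (or ground truth).
#' @return the motion-corrected [ca_movie()].
#' @export
apply_shifts <- function(m, shifts) {
  Tn <- n_frames(m)
  if (nrow(shifts) != Tn) stop("shift series length does not match movie")
  out <- m
  for (t in seq_len(Tn)) {
    if (shifts$dy_px[t] != 0 || shifts$dx_px[t] != 0) {
      out$frames[, , t] <- translate_int(m$frames[, , t],
                                         -shifts$dy_px[t], -shifts$dx_px[t])
    }
  }
  out
}

#' Anscombe variance-stabilizing transform and its inverse
#'
#' `anscombe()` maps x to `2 * sqrt(x + 3/8)`, approximately unit-variance
#' for Poisson counts; `inverse_anscombe()` is the algebraic inverse.
#'
#' @param x non-negative numeric (vector, matrix, array or [ca_movie()]).
#' @return transformed object of the same shape/class.
#' @export
anscombe <- function(x) {
  if (inherits(x, "ca_movie")) {
    x$frames <- anscombe(x$frames); return(x)
  }
  if (any(x < 0)) stop("Anscombe transform requires non-negative input")
  2 * sqrt(x + 3 / 8)
}

#' @rdname anscombe
#' @export
inverse_anscombe <- function(x) {
  if (inherits(x, "ca_movie")) {
    x$frames <- inverse_anscombe(x$frames); return(x)
  }
  (x / 2)^2 - 3 / 8
}

#' Patch-based truncated-SVD denoising
#'
#' The movie is divided into overlapping square spatial patches; in each
#' patch the pixels-by-time matrix is approximated by a truncated SVD whose
#' spatial (left) factors are Gaussian-smoothed, and the overlapping patch
#' reconstructions are blended with weights that sum to one at every pixel.
#' With `transform = TRUE` (the default) the movie is Anscombe transformed
#' first and inverse-transformed at the end, so the rank truncation operates
#' on variance-stabilized data.
#'
#' @param m a [ca_movie()] (motion-corrected counts).
#' @param patch patch side, pixels (default 64).
#' @param overlap overlap between neighbouring patches, pixels
#'   (default `patch / 2`).
#' @param rank SVD truncation rank per patch (default 8).
#' @param sigma_spatial Gaussian sigma for smoothing the spatial factors,
#'   pixels (default 0.5, about half the optical point-spread scale; 0 disables).
#' @param transform apply the Anscombe pair around the approximation.
#' @return the denoised [ca_movie()].
#' @export
patch_svd_denoise <- function(m, patch = 64L, overlap = NULL, rank = 8L,
                              sigma_spatial = 0.5, transform = TRUE) {
  d <- dim(m$frames)
  patch <- as.integer(min(patch, d[1], d[2]))
  if (is.null(overlap)) overlap <- patch %/% 2L
  overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= patch)
    stop("`overlap` must satisfy 0 <= overlap < patch")
  rank_max <- min(patch^2, d[3])
  if (rank > rank_max) {
    warning("rank clipped to ", rank_max)
    rank <- rank_max
  }
  X <- if (transform) anscombe(m$frames) else m$frames

  starts <- function(extent) {
    s <- seq(1L, max(extent - patch + 1L, 1L), by = patch - overlap)
    unique(c(s, extent - patch + 1L))
  }
  ys <- starts(d[1]); xs <- starts(d[2])
  num <- array(0, d)
  den <- array(0, d[1:2])
  for (y0 in ys) for (x0 in xs) {
    yi <- y0:(y0 + patch - 1L); xi <- x0:(x0 + patch - 1L)
    M <- matrix(X[yi, xi, ], patch^2, d[3])
    mu <- rowMeans(M)
    sv <- trunc_svd(M - mu, min(rank, patch^2, d[3]))
    U <- sv$u
    if (sigma_spatial > 0) {
      for (j in seq_len(ncol(U))) {
        U[, j] <- as.numeric(EBImage::gblur(matrix(U[, j], patch, patch),
                                            sigma = sigma_spatial))
      }
    }
    Mhat <- U %*% (diag(sv$d, nrow = length(sv$d)) %*% t(sv$v)) + mu
    num[yi, xi, ] <- num[yi, xi, ] + array(Mhat, c(patch, patch, d[3]))
    den[yi, xi] <- den[yi, xi] + 1
  }
  X <- num / array(den, d)   # blend weights sum to 1 at every pixel
  if (transform) {
    X <- inverse_anscombe(X)
    X[X < 0] <- 0
  }
  out <- m
  out$frames <- X
  out
}

#' Run the full preprocessing chain
#'
#' Temporal binning, reference denoising on the red channel, shift
#' estimation and application to both channels, then Anscombe/patch-SVD
#' denoising of the green channel — in the order bin, correct, denoise.
#'
#' @param green,red raw [ca_movie()]s.
#' @param batch temporal bin size.
#' @param n_components,sigma_px reference-denoising parameters.
#' @param patch,overlap,rank,sigma_spatial patch-SVD parameters.
#' @return list with denoised `green`, corrected `red`, and `shifts`.
#' @export
preprocess_movies <- function(green, red, batch = 5L,
                              n_components = 50L, sigma_px = 1,
                              patch = 64L, overlap = NULL, rank = 8L,
                              sigma_spatial = 0.5) {
  gb <- temporal_bin(green, batch)
  rb <- temporal_bin(red, batch)
  rd <- denoise_reference(rb, n_components, sigma_px)
  sh <- estimate_shifts(rd)
  gc <- apply_shifts(gb, sh)
  rc <- apply_shifts(rb, sh)
  gd <- patch_svd_denoise(gc, patch = patch, overlap = overlap, rank = rank,
                          sigma_spatial = sigma_spatial)
  list(green = gd, red = rc, shifts = sh)
}
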