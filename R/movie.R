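#' Fluorescence movie container
#'
#' A light S3 container for a time-ordered stack of 2-D fluorescence frames.
#' Frames are stored as an `H x W x T` numeric array together with the frame
#' rate and a channel tag (`"green"` for the calcium indicator, `"red"` for
#' the autofluorescence morphology channel).
#'
#' @param frames numeric array `H x W x T` of non-negative finite intensities;
#'   a single matrix is promoted to a one-frame movie.
#' @param fs sampling rate in Hz (frames per second).
#' @param channel `"green"` or `"red"`.
#' @param pixel_size_um optional pixel pitch in micrometres.
#' @return an object of class `ca_movie`.
#' @export
ca_movie <- function(frames, fs, channel = c("green", "red"),
                     pixel_size_um = NULL) {
  channel <- match.arg(channel)
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be an H x W x T array")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive frame rate in Hz")
  if (anyNA(frames) || any(!is.finite(frames)))
    stop("movie intensities must be finite")
  if (any(frames < 0))
    stop("movie intensities must be non-negative")
  structure(list(frames = frames, fs = fs, channel = channel,
                 pixel_size_um = pixel_size_um),
            class = "ca_movie")
}

#' @export
dim.ca_movie <- function(x) dim(x$frames)

n_frames <- function(m) dim(m$frames)[3L]

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ca_movie> %s channel, %d x %d px, %d frames @ %.3g Hz\n",
              x$channel, d[1], d[2], d[3], x$fs))
  invisible(x)
}

# frames as a pixels x time matrix (column = frame)
as_pixel_matrix <- function(m) {
  d <- dim(m$frames)
  matrix(m$frames, d[1] * d[2], d[3])
}

movie_from_pixel_matrix <- function(mat, template) {
  d <- dim(template$frames)
  stopifnot(nrow(mat) == d[1] * d[2])
  out <- template
  out$frames <- array(mat, c(d[1], d[2], ncol(mat)))
  out
}
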