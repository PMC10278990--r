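# Shared file formats: multi-page TIFF movies (uint16), speed and trace
# CSVs, label-image ROI masks, and JSON parameter echoes.

#' Read and write fluorescence movies as multi-page TIFF
#'
#' Movies are stored one channel per file as 16-bit multi-page TIFF;
#' intensities are integer counts in `[0, 65535]`. The write/read round
#' trip preserves values exactly.
#'
#' @param m a [ca_movie()] with integer-valued counts.
#' @param path file path.
#' @param fs,channel movie metadata for [read_movie()] (TIFF carries none).
#' @return `read_movie()` returns a [ca_movie()].
#' @export
write_movie <- function(m, path) {
  fr <- m$frames
  if (max(fr) > 65535) stop("intensities exceed uint16 range")
  pages <- lapply(seq_len(dim(fr)[3]),
                  function(t) fr[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path, fs, channel = "green") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  fr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    fr[, , t] <- round(p * 65535)
  }
  ca_movie(fr, fs = fs, channel = channel)
}

#' Read and write locomotion speed traces
#'
#' CSV with columns `time_s`, `speed_cm_s`.
#'
#' @param speed data.frame with those columns.
#' @param path file path.
#' @return `read_speed()` returns the data.frame.
#' @export
write_speed <- function(speed, path) {
  utils::write.csv(speed[, c("time_s", "speed_cm_s")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_speed
#' @export
read_speed <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "speed_cm_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("speed CSV is missing column(s): ", paste(miss, collapse = ", "))
  df[, need]
}

#' Write and read ROI label masks
#'
#' Label images are stored as 16-bit TIFF. The convention pairs each
#' astrocyte domain (label `i`) with its soma (label `i + soma_offset`);
#' `read_masks()` parses the label image into per-cell domain, soma and
#' processes masks.
#'
#' @param labels integer label matrix.
#' @param path file path.
#' @param soma_offset soma label offset (default 1000).
#' @return `read_masks()` returns a list of cells, each with logical
#'   `domain`, `soma`, `processes`.
#' @export
write_masks <- function(labels, path) {
  if (max(labels) > 65535) stop("labels exceed uint16 range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path, soma_offset = 1000L) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  lab <- round(p * 65535)
  ids <- sort(unique(lab[lab > 0 & lab <= soma_offset]))
  lapply(ids, function(i) {
    soma <- lab == i + soma_offset
    domain <- (lab == i) | soma
    list(id = i, domain = domain, soma = soma,
         processes = domain & !soma)
  })
}

#' Write a ground-truth / parameter echo JSON
#'
#' @param x a list (configuration, ground truth, manifest, ...).
#' @param path file path.
#' @export
write_json_log <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
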