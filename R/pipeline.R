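# End-to-end orchestration of the analysis stages in their methodological
# order: binning -> motion correction -> denoising -> dF/F -> branch
# analysis (astrocyte or neuron) -> locomotion statistics.

#' Run the full analysis pipeline on a recording
#'
#' Takes a green/red movie pair and a speed trace, preprocesses them
#' (temporal binning, red-channel-driven rigid motion correction,
#' Anscombe/patch-SVD denoising), computes pixel-wise dF/F and the active
#' area, runs the branch-specific analysis (astrocyte compartments or
#' neuronal activity-unit segmentation), and computes locomotion-coupling
#' statistics. Deterministic for a fixed input and configuration.
#'
#' @param green,red raw [ca_movie()]s sharing a time base.
#' @param speed data.frame `time_s`, `speed_cm_s`.
#' @param branch `"astro"` or `"neuro"`.
#' @param cells for the astro branch, a list of ROI masks (each with
#'   `domain`, `soma`, `processes`), e.g. from [read_masks()].
#' @param params named list overriding defaults: `batch`, `patch`, `rank`,
#'   `sigma_spatial`, `dff_threshold`, `min_pixels`, `min_frames`,
#'   `speed_thr`, `max_gap_s`, `n_final`, `k_per_patch`, `nmf_patch`.
#' @param out_dir optional directory; when given, tables, the resolved
#'   configuration and a manifest are written there.
#' @return list with `preprocessed`, `dff`, `active_area`, `mean_dff`,
#'   `episodes`, `branch` results, and `stats` (Q/L, cross-correlation,
#'   paired runs, PRR).
#' @export
run_pipeline <- function(green, red, speed, branch = c("astro", "neuro"),
                         cells = NULL, params = list(), out_dir = NULL) {
  branch <- match.arg(branch)
  p <- utils::modifyList(list(batch = 5L, n_components = 50L, sigma_px = 1,
                              patch = 64L, rank = 8L, sigma_spatial = 0.5,
                              sigma_t = 15, dff_threshold = 15,
                              min_pixels = 16L, min_frames = 3L,
                              speed_thr = 0.5, max_gap_s = 30,
                              nmf_patch = 100L, k_per_patch = 12L,
                              n_final = 12L, max_lag_s = 15, post_s = 10),
                         params)
  if (branch == "astro" && is.null(cells))
    stop("astro branch requires ROI masks (`cells`); none were provided")

  pre <- preprocess_movies(green, red, batch = p$batch,
                           n_components = min(p$n_components,
                                              n_frames(green) %/% p$batch - 1L),
                           sigma_px = p$sigma_px, patch = p$patch,
                           rank = p$rank, sigma_spatial = p$sigma_spatial)
  d <- dff_movie_pipeline(pre$green, sigma_t = p$sigma_t)
  segs <- detect_active_segments(d, thr = p$dff_threshold,
                                 min_pixels = p$min_pixels,
                                 min_frames = p$min_frames)
  aa <- active_area_trace(segs)
  md <- frame_mean_dff(d)
  episodes <- segment_episodes(speed, speed_thr = p$speed_thr)

  fs_b <- d$fs
  branch_res <- if (branch == "astro") {
    list(cells = astro_cell_table(d, cells))
  } else {
    units <- segment_neuro_movie(d, patch = p$nmf_patch,
                                 k_per_patch = p$k_per_patch,
                                 n_final = p$n_final)
    list(units = units,
         labels = if (length(units))
           unit_classification(units, episodes, fs_b) else character(0))
  }

  pairs <- find_paired_runs(episodes, max_gap_s = p$max_gap_s)
  prr <- if (nrow(pairs)) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      r_d <- paired_run_ratio(md$mean_dff_pct, fs_b, pairs[i, ],
                              post_s = p$post_s)
      r_a <- paired_run_ratio(aa$active_area_pct, fs_b, pairs[i, ],
                              post_s = p$post_s)
      data.frame(pair = i, gap_s = pairs$gap_s[i],
                 prr_dff_peak = r_d$prr_peak, prr_dff_mean = r_d$prr_mean,
                 prr_area_peak = r_a$prr_peak, prr_area_mean = r_a$prr_mean)
    }))
  } else NULL
  xc <- speed_dff_crosscorr(md$mean_dff_pct,
                            resample_to(speed$speed_cm_s, length(md$mean_dff_pct)),
                            fs_b, max_lag_s = p$max_lag_s)
  stats <- list(
    ql_dff = ql_ratio(md$mean_dff_pct, fs_b, episodes),
    ql_area = ql_ratio(aa$active_area_pct, fs_b, episodes),
    crosscorr_r = xc$r, crosscorr_lag_s = xc$lag_s,
    episode_means_dff = episode_means(md$mean_dff_pct, fs_b, episodes),
    episode_means_area = episode_means(aa$active_area_pct, fs_b, episodes),
    pairs = pairs, prr = prr)

  res <- list(preprocessed = pre, dff = d, active_area = aa, mean_dff = md,
              episodes = episodes, branch = branch_res, stats = stats,
              params = p)
  if (!is.null(out_dir)) write_pipeline_outputs(res, branch, out_dir)
  res
}

# block-average a raw-rate trace onto n frames
resample_to <- function(x, n) {
  g <- floor(seq_along(x) / (length(x) / n) - 1e-9)
  out <- as.numeric(tapply(x, g, mean))
  out[seq_len(n)]
}

write_pipeline_outputs <- function(res, branch, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cbind(res$active_area,
                         mean_dff_pct = res$mean_dff$mean_dff_pct),
                   file.path(out_dir, "activity.csv"), row.names = FALSE)
  utils::write.csv(res$preprocessed$shifts,
                   file.path(out_dir, "shifts.csv"), row.names = FALSE)
  utils::write.csv(res$episodes, file.path(out_dir, "episodes.csv"),
                   row.names = FALSE)
  if (!is.null(res$stats$prr))
    utils::write.csv(res$stats$prr, file.path(out_dir, "prr.csv"),
                     row.names = FALSE)
  if (branch == "astro" && !is.null(res$branch$cells))
    utils::write.csv(res$branch$cells, file.path(out_dir, "astro_cells.csv"),
                     row.names = FALSE)
  manifest <- list(package = "caflux",
                   version = as.character(utils::packageVersion("caflux")),
                   branch = branch,
                   params = res$params,
                   stats = res$stats[c("ql_dff", "ql_area", "crosscorr_r",
                                       "crosscorr_lag_s")])
  write_json_log(manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
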