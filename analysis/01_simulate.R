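#!/usr/bin/env Rscript
# Generate one astrocyte and one neuron example recording with ground
# truth, and write the raw data (movies, speed, ROI masks, truth echo)
# under results/data/. Downstream scripts start from these files.

suppressMessages(library(caflux))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

astro_cfg <- scenario_config(duration_s = 120, fs_raw = 30, fov = 72L,
                             n_astro = 2L, n_neuro_units = 0L,
                             mean_run_s = 18, paired_prob = 1,
                             max_shift_px = 2L,
                             domain_radius_px = 15, soma_radius_px = 5,
                             seed = 1L)
neuro_cfg <- scenario_config(duration_s = 120, fs_raw = 30, fov = 72L,
                             n_astro = 0L, n_neuro_units = 8L,
                             mean_run_s = 18, paired_prob = 1,
                             max_shift_px = 2L, seed = 2L)

for (branch in c("astro", "neuro")) {
  cfg <- if (branch == "astro") astro_cfg else neuro_cfg
  rec <- simulate_recording(cfg)
  write_movie(rec$noisy$green, file.path(out, paste0(branch, "_green.tif")))
  write_movie(rec$noisy$red, file.path(out, paste0(branch, "_red.tif")))
  write_speed(rec$speed$speed, file.path(out, paste0(branch, "_speed.csv")))
  if (branch == "astro")
    write_masks(rec$truth$scene$labels, file.path(out, "astro_masks.tif"))
  write_json_log(list(config = unclass(cfg),
                      episodes = rec$truth$episodes,
                      pairs = rec$truth$pairs,
                      shifts = rec$truth$shifts),
                 file.path(out, paste0(branch, "_truth.json")))
  msg <- sprintf("%s: %d frames, %d locomotion episodes, %d paired runs",
                 branch, 120 * 30,
                 sum(rec$truth$episodes$label == "locomotion"),
                 nrow(rec$truth$pairs))
  cat(msg, "\n")
}
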