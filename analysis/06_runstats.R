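#!/usr/bin/env Rscript
# Locomotion-coupling statistics for both recordings: per-episode means,
# Q/L ratios, speed/dF-F cross-correlation peak and lag, paired-run
# detection and PRR, and the astro-vs-neuro rank test.

suppressMessages(library(caflux))
out <- "results/runstats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

stats <- list()
for (branch in c("astro", "neuro")) {
  act <- utils::read.csv(file.path("results/activity",
                                   paste0(branch, "_activity.csv")))
  speed <- read_speed(file.path("results/data", paste0(branch, "_speed.csv")))
  fs <- 6
  episodes <- segment_episodes(speed)
  md <- act$mean_dff_pct
  aa <- act$active_area_pct
  g <- floor(seq_along(speed$speed_cm_s) /
               (length(speed$speed_cm_s) / length(md)) - 1e-9)
  sp_b <- as.numeric(tapply(speed$speed_cm_s, g, mean))[seq_along(md)]
  xc <- speed_dff_crosscorr(md, sp_b, fs)
  pairs <- find_paired_runs(episodes)
  prr <- if (nrow(pairs)) paired_run_ratio(md, fs, pairs[1, ])$prr_peak else NA
  em <- episode_means(md, fs, episodes)
  utils::write.csv(em, file.path(out, paste0(branch, "_episode_means.csv")),
                   row.names = FALSE)
  stats[[branch]] <- list(ql_dff = ql_ratio(md, fs, episodes),
                          ql_area = ql_ratio(aa, fs, episodes),
                          crosscorr_r = xc$r, crosscorr_lag_s = xc$lag_s,
                          n_pairs = nrow(pairs), prr_dff = prr)
  cat(sprintf("%s: Q/L(dF/F) %.3f, lag %.2f s (r = %.2f), PRR %s\n",
              branch, stats[[branch]]$ql_dff, xc$lag_s, xc$r,
              ifelse(is.na(prr), "-", sprintf("%.2f", prr))))
}

# episode-level rank test of locomotion dF/F between the two recordings
em_a <- utils::read.csv(file.path(out, "astro_episode_means.csv"))
em_n <- utils::read.csv(file.path(out, "neuro_episode_means.csv"))
mw <- mann_whitney(em_a$mean[em_a$label == "locomotion"],
                   em_n$mean[em_n$label == "locomotion"])
stats$locomotion_dff_mw <- mw
write_json_log(stats, file.path(out, "summary.json"))
cat(sprintf("locomotion dF/F astro vs neuro: U = %g, p = %.3g (%s)\n",
            mw$U, mw$p_value, mw$method))
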