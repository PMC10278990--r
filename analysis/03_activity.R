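#!/usr/bin/env Rscript
# Pixel-wise dF/F (envelope baseline + mode bias correction), active-segment
# detection (>= 15% dF/F, clusters > 16 px, >= 3 consecutive frames) and the
# active-area / mean-dF/F timecourses for both recordings.

suppressMessages(library(caflux))
ind <- "results/preprocessed"
out <- "results/activity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (branch in c("astro", "neuro")) {
  g <- read_movie(file.path(ind, paste0(branch, "_green_denoised.tif")),
                  fs = 6, channel = "green")
  d <- dff_movie_pipeline(g)
  segs <- detect_active_segments(d)
  aa <- active_area_trace(segs)
  md <- frame_mean_dff(d)
  tab <- cbind(aa, mean_dff_pct = md$mean_dff_pct)
  utils::write.csv(tab, file.path(out, paste0(branch, "_activity.csv")),
                   row.names = FALSE)
  cat(sprintf("%s: peak active area %.1f%%, peak mean dF/F %.1f%%, %d segments\n",
              branch, max(aa$active_area_pct), max(md$mean_dff_pct),
              length(unique(segs$segments$segment))))
}
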