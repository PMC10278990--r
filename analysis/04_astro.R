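#!/usr/bin/env Rscript
# Astrocyte-branch analysis of the astro example recording: soma/process
# timecourses, 15%-of-peak onset latency, Morlet band power (0.1-0.3 Hz),
# Feret diameters and the latency-vs-size regression.

suppressMessages(library(caflux))
out <- "results/astro"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

g <- read_movie("results/preprocessed/astro_green_denoised.tif", fs = 6,
                channel = "green")
cells <- read_masks("results/data/astro_masks.tif")
d <- dff_movie_pipeline(g)
tab <- astro_cell_table(d, cells)
utils::write.csv(tab, file.path(out, "astro_cells.csv"), row.names = FALSE)
cat(sprintf("%d cells; latency median %.2f s; soma/process peak ratio %.2f\n",
            nrow(tab), stats::median(tab$latency_s, na.rm = TRUE),
            stats::median(tab$soma_peak_pct / tab$proc_peak_pct)))
if (sum(is.finite(tab$latency_s)) >= 3 && stats::var(tab$feret) > 0) {
  reg <- latency_size_regression(tab$latency_s, tab$feret)
  write_json_log(reg, file.path(out, "latency_size_regression.json"))
  cat(sprintf("latency ~ Feret: R^2 = %.3f, p = %.3f (n = %d)\n",
              reg$r_squared, reg$p_value, reg$n))
} else {
  cat("too few cells for the latency-size regression in this example\n")
}
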