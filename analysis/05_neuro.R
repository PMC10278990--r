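#!/usr/bin/env Rscript
# Neuron-branch analysis of the neuro example recording: patch-based
# non-negative factorization, Li-threshold footprint clipping, Ward merging
# into activity units, and quiescent/locomotion classification.

suppressMessages(library(caflux))
out <- "results/neuro"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

g <- read_movie("results/preprocessed/neuro_green_denoised.tif", fs = 6,
                channel = "green")
speed <- read_speed("results/data/neuro_speed.csv")
d <- dff_movie_pipeline(g)
units <- segment_neuro_movie(d, patch = 48L, k_per_patch = 3L, n_final = 8L)
episodes <- segment_episodes(speed)
labels <- unit_classification(units, episodes, d$fs)

fp <- lapply(units, `[[`, "footprint")
write_movie(ca_movie(array(round(do.call(c, fp) /
                                   max(unlist(fp)) * 10000),
                           c(dim(fp[[1]]), length(fp))),
                     fs = 1, channel = "green"),
            file.path(out, "unit_footprints.tif"))
tr <- sapply(units, `[[`, "trace")
colnames(tr) <- paste0("unit_", seq_along(units))
utils::write.csv(cbind(time_s = (seq_len(nrow(tr)) - 1) / d$fs, tr),
                 file.path(out, "unit_traces.csv"), row.names = FALSE)
write_json_log(list(labels = labels,
                    members = lapply(units, `[[`, "members")),
               file.path(out, "unit_labels.json"))
cat(sprintf("%d units: %d locomotion-active, %d quiescent-active\n",
            length(units), sum(labels == "locomotion_active"),
            sum(labels == "quiescent_active")))
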