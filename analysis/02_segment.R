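#!/usr/bin/env Rscript
# Stage 2: segment microcolonies in every simulated scene.
#
# Runs the 2D pipeline (Gaussian smoothing, Otsu foreground, dark-ridge
# subtraction, prominence-seeded watershed, small-object removal) on each
# scene from stage 1, extracts per-colony features (position, orientation,
# length/width, channel brightness), calls colony genotypes from channel
# brightness, and writes one colony table per preset.

suppressMessages(library(printarray))

presets <- c("segregated", "strips2", "strips4", "checkerboard", "mixed")
dir.create("results/colonies", recursive = TRUE, showWarnings = FALSE)

summary_rows <- lapply(presets, function(p) {
  img <- read_micrograph(file.path("results/scenes", paste0(p, ".tif")))
  truth <- read_colony_table(file.path("results/scenes",
                                       paste0(p, "_truth.csv")))
  lab <- segment_microcolonies_2d(img)
  fe <- call_colony_genotypes(extract_colony_features(lab, img))
  write_colony_table(fe, file.path("results/colonies", paste0(p, ".csv")))
  data.frame(preset = p, truth_colonies = nrow(truth), labels = lab$n,
             median_length_um = round(stats::median(fe$length_um), 1))
})
summary_df <- do.call(rbind, summary_rows)
print(summary_df, row.names = FALSE)
utils::write.csv(summary_df, "results/segmentation_summary.csv",
                 row.names = FALSE)

cat("\nNote: at full droplet occupancy colonies overlap heavily inside",
    "droplets,\nso the label count sits well below the founder-cell count;",
    "counts match the\nground truth exactly only on sparse non-touching",
    "scenes (see the tests).\n")
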