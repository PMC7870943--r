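#!/usr/bin/env Rscript
# Stage 1: simulate printed arrays at graded degrees of genetic mixing.
#
# Builds the five preset 7x8 printing maps (fully segregated halves, two
# approximate intermediate strip layouts, checkerboard, fully mixed), then
# renders one synthetic two-channel micrograph per preset at the study
# conditions: tangent 110-um droplets, 1e8 cells/mL (~70 founder cells per
# droplet), colonies at median diameter 15 um, 1.515 um/px, plus background,
# gradient and additive noise. Each scene keeps its ground truth.

suppressMessages(library(printarray))

out_maps <- "results/maps"
out_scenes <- "results/scenes"
dir.create(out_maps, recursive = TRUE, showWarnings = FALSE)
dir.create(out_scenes, recursive = TRUE, showWarnings = FALSE)

presets <- c("segregated", "strips2", "strips4", "checkerboard", "mixed")
seed <- 1L

for (p in presets) {
  map <- preset_map(p)
  write_printing_map(map, file.path(out_maps, paste0(p, ".json")))
  scene <- render_scene(map, seed = seed)
  write_scene(scene, file.path(out_scenes, p))
  cat(sprintf("%-13s %4d colonies rendered (approximate layout: %s)\n",
              p, nrow(scene$colonies),
              ifelse(isTRUE(attr(map, "approximate")), "yes", "no")))
}

cat("\nScenes and printing maps written under results/maps and",
    "results/scenes.\n")
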