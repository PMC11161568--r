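#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study material.
#
# Builds one ten-cell panel per nominal pitch (280, 320, 360 nm; band
# centres 420/480/540 nm spanning violet-blue to green), each panel with
# per-cell pitch variability (CV 5 %), paired LCP/RCP spectra, transverse
# band images and one oblique arc image, and writes them in the pipeline's
# file layout under scratch/panels/.

suppressPackageStartupMessages(library(helicoidr))

seed <- 20240329L
pitches <- c(280, 320, 360)
out_root <- "scratch/panels"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

for (pitch in pitches) {
  hp <- helicoid_params(pitch, "left", n_turns = 40)
  panel <- simulate_species_panel(hp, n_cells = 10, pitch_cv = 0.05,
                                  seed = seed + pitch)
  dir <- file.path(out_root, sprintf("pitch_%d", pitch))
  write_species_panel(panel, dir)
  cat(sprintf(
    "pitch %d nm: wrote %d cells (band centre %.0f nm, expected half-pitch %.0f nm) -> %s\n",
    pitch, length(panel$cells), hp$n_mean * pitch, pitch / 2, dir
  ))
}
cat("done: synthetic panels under", out_root, "\n")
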