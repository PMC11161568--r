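#!/usr/bin/env Rscript
# Stage 3: lamellar half-pitch from the TEM-style band images.
#
# For every panel: per-image band-normal profile (structure-tensor
# orientation), groups-of-ten half-pitch and the autocorrelation
# cross-check, plus the arc score of the panel's oblique-section image.
# Writes results/pitch_images.csv and results/pitch_panels.csv.

suppressPackageStartupMessages(library(helicoidr))

panels <- list.dirs("scratch/panels", recursive = FALSE)
if (!length(panels)) stop("run analysis/01_simulate.R first")
dir.create("results", showWarnings = FALSE)

img_rows <- list()
panel_rows <- list()
for (dir in panels) {
  tifs <- list.files(file.path(dir, "images"), pattern = "^cell.*\\.tif$",
                     full.names = TRUE)
  rows <- do.call(rbind, lapply(tifs, function(p) {
    prof <- extract_profile(read_band_image(p))
    g10 <- group_of_ten_measure(prof)
    ac <- estimate_band_period(prof)
    data.frame(panel = basename(dir),
               image_id = tools::file_path_sans_ext(basename(p)),
               half_pitch_g10_nm = g10$half_pitch_nm,
               half_pitch_autocorr_nm = ac$half_pitch_nm,
               n_groups = g10$n_groups,
               flags = paste(ac$flags, collapse = ";"))
  }))
  img_rows[[dir]] <- rows
  score <- arc_score(read_band_image(file.path(dir, "images", "arc.tif")))
  truth <- read_run_config(file.path(dir, "truth.meta"))
  panel_rows[[dir]] <- data.frame(
    panel = basename(dir),
    half_pitch_nm = mean(rows$half_pitch_g10_nm),
    sd_nm = stats::sd(rows$half_pitch_g10_nm),
    n_images = nrow(rows), arc_score = score,
    true_half_pitch_nm = truth$pitch_nm / 2
  )
  cat(sprintf("%s: half-pitch %.1f ± %.1f nm over %d images (truth %.0f), arc score %.2f\n",
              basename(dir), mean(rows$half_pitch_g10_nm),
              stats::sd(rows$half_pitch_g10_nm), nrow(rows),
              truth$pitch_nm / 2, score))
}
utils::write.csv(do.call(rbind, img_rows), "results/pitch_images.csv",
                 row.names = FALSE, quote = FALSE)
utils::write.csv(do.call(rbind, panel_rows), "results/pitch_panels.csv",
                 row.names = FALSE, quote = FALSE)
cat("wrote results/pitch_images.csv, results/pitch_panels.csv\n")
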