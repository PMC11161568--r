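#' Run the full four-step diagnostic pipeline on a data directory
#'
#' Executes spectra -> optics -> TEM pitch -> concordance on files laid out
#' as written by [write_species_panel()]: per-cell LCP/RCP spectrum files
#' listed in `spectra/manifest.csv`, per-cell band TIFFs (with `.meta`
#' sidecars) under `images/`, and an optional oblique-section `arc.tif`.
#' Writes the per-cell peak table, per-image pitch table, concordance row
#' (display + raw) and verdict under `out_dir`, plus a `run.log` recording
#' package version, seed and thresholds. All analysis stages are
#' deterministic, so repeated runs on the same inputs are byte-identical.
#'
#' @param config Named list or path to a `key = value` config file. Keys
#'   (all optional except `input_dir`): `input_dir`, `out_dir` (default
#'   `<input_dir>/results`), `species`, `n_mean` (1.50), `step_nm` (1),
#'   `range_lo`/`range_hi` (400/800), `smooth_window` (5), `window_nm` (20),
#'   `ratio_threshold` (2), `prominence_frac` (0.05), `rel_tol` (0.08),
#'   `arc_threshold` (0.5), `seed` (1).
#' @return Invisibly, a list with `summary`, `pitch`, `arc_score`, `row`,
#'   `verdict`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(
    out_dir = NULL, species = "synthetic species", n_mean = 1.50,
    step_nm = 1, range_lo = 400, range_hi = 800, smooth_window = 5,
    window_nm = 20, ratio_threshold = 2, prominence_frac = 0.05,
    rel_tol = 0.08, arc_threshold = 0.5, seed = 1
  ), config)
  if (is.null(cfg$input_dir)) stop("config must name input_dir")
  out_dir <- cfg$out_dir %||% file.path(cfg$input_dir, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  oc <- optical_constants(cfg$n_mean)

  # --- stage: spectra -------------------------------------------------
  manifest_path <- file.path(cfg$input_dir, "spectra", "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("spectra stage: manifest file not found: ", manifest_path)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  per_cell <- do.call(rbind, lapply(split(manifest, manifest$cell_id),
    function(m) {
      lcp <- read_spectrum(m$path[m$channel == "LCP"][1], "LCP", m$cell_id[1])
      rcp <- read_spectrum(m$path[m$channel == "RCP"][1], "RCP", m$cell_id[1])
      pair <- structure(list(lcp = lcp, rcp = rcp, cell_id = m$cell_id[1],
                             common_grid = FALSE, flags = character()),
                        class = "cell_spectrum_pair")
      pair <- resample_to_common_grid(pair, cfg$step_nm)
      analyze_pair(pair, c(cfg$range_lo, cfg$range_hi), cfg$smooth_window,
                   cfg$window_nm, cfg$ratio_threshold, cfg$prominence_frac)
    }))
  per_cell <- per_cell[order(per_cell$cell_id), , drop = FALSE]
  utils::write.csv(per_cell, file.path(out_dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  summary <- summarize_cells(per_cell)

  # --- stage: TEM pitch ----------------------------------------------
  image_dir <- file.path(cfg$input_dir, "images")
  tifs <- sort(list.files(image_dir, pattern = "\\.tif$", full.names = TRUE))
  arc_path <- tifs[basename(tifs) == "arc.tif"]
  band_paths <- setdiff(tifs, arc_path)
  if (!length(band_paths)) stop("tem stage: no band image TIFFs under ",
                                image_dir)
  pitch_rows <- do.call(rbind, lapply(band_paths, function(p) {
    img <- read_band_image(p)
    prof <- extract_profile(img)
    est <- group_of_ten_measure(prof)
    hp <- est$half_pitch_nm
    if (!is.na(img$tilt_deg) && img$tilt_deg != 0) {
      hp <- correct_obliquity(hp, img$tilt_deg)
    }
    data.frame(image_id = tools::file_path_sans_ext(basename(p)),
               method = est$method, half_pitch_nm = hp, sd_nm = est$sd_nm,
               n_groups = est$n_groups)
  }))
  utils::write.csv(pitch_rows, file.path(out_dir, "pitch.csv"),
                   row.names = FALSE, quote = FALSE)
  pitch <- structure(
    list(half_pitch_nm = mean(pitch_rows$half_pitch_nm),
         sd_nm = if (nrow(pitch_rows) > 1) stats::sd(pitch_rows$half_pitch_nm)
                 else pitch_rows$sd_nm[1],
         n_groups = nrow(pitch_rows), method = "group_of_ten",
         flags = character()),
    class = "pitch_estimate"
  )

  # --- stage: arcs ----------------------------------------------------
  score <- if (length(arc_path)) arc_score(read_band_image(arc_path[1]))
           else NA_real_
  arcs <- if (is.na(score)) NA else score >= cfg$arc_threshold

  # --- stage: concordance --------------------------------------------
  row <- build_concordance(summary, pitch, if (is.na(score)) TRUE else score,
                           oc, species = cfg$species, rel_tol = cfg$rel_tol,
                           arc_threshold = cfg$arc_threshold)
  render_table(row, file.path(out_dir, "concordance.txt"),
               file.path(out_dir, "concordance.csv"))
  verdict <- four_step_verdict(summary, pitch, arcs, row$agreement)
  writeLines(utils::capture.output(print(verdict)),
             file.path(out_dir, "verdict.txt"))

  writeLines(c(
    paste0("helicoidr_version = ",
           as.character(utils::packageVersion("helicoidr"))),
    paste0("seed = ", cfg$seed),
    paste0("n_mean = ", cfg$n_mean),
    paste0("ratio_threshold = ", cfg$ratio_threshold),
    paste0("prominence_frac = ", cfg$prominence_frac),
    paste0("rel_tol = ", cfg$rel_tol),
    paste0("arc_threshold = ", cfg$arc_threshold),
    paste0("n_cells = ", summary$n_cells),
    paste0("n_band_images = ", nrow(pitch_rows))
  ), file.path(out_dir, "run.log"))

  invisible(list(summary = summary, pitch = pitch, arc_score = score,
                 row = row, verdict = verdict, out_dir = out_dir))
}
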