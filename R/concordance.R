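#' Do predicted and observed half-pitch agree?
#'
#' The structure-colour concordance step needs an explicit rule for
#' "correlated well": agreement holds when the absolute difference is within
#' the combined one-SD uncertainty or within `rel_tol` of the predicted
#' value, whichever is larger:
#' `|pred - obs| <= max(sqrt(sd_pred^2 + sd_obs^2), rel_tol * pred)`.
#'
#' @param pred,obs Predicted and observed half-pitch, nm (> 0).
#' @param sd_pred,sd_obs Their SDs, nm (>= 0).
#' @param rel_tol Relative tolerance floor (default 0.08).
#' @return Logical.
#' @examples
#' assess_agreement(161, 157, 9, 8) # TRUE
#' assess_agreement(161, 100, 0, 0) # FALSE
#' @export
assess_agreement <- function(pred, obs, sd_pred = 0, sd_obs = 0,
                             rel_tol = 0.08) {
  if (any(pred <= 0) || any(obs <= 0)) stop("lengths must be positive")
  abs(pred - obs) <= pmax(sqrt(sd_pred^2 + sd_obs^2), rel_tol * pred)
}

#' Build one species-level concordance row
#'
#' Combines the spectral panel summary (mean peak +/- SD), the TEM pitch
#' estimate, and the arc evidence into one record: the predicted half-pitch
#' `mean_peak / (2 n_mean)` with propagated SD, the observed half-pitch, the
#' arc call, and the agreement verdict.
#'
#' @param summary A `"panel_summary"` (or list with `mean_peak_nm`,
#'   `sd_peak_nm`, `n_cells`).
#' @param pitch A `"pitch_estimate"` (or list with `half_pitch_nm`,
#'   `sd_nm`).
#' @param arcs Either a logical (human-judged arc presence) or a numeric
#'   [arc_score()] value thresholded at `arc_threshold`.
#' @param oc [optical_constants()].
#' @param species Species label; empty names get a placeholder id.
#' @param rel_tol Passed to [assess_agreement()].
#' @param arc_threshold Arc-score threshold (default 0.5).
#' @return One-row data frame of class `"concordance_row"`.
#' @export
build_concordance <- function(summary, pitch, arcs, oc = optical_constants(),
                              species = "", rel_tol = 0.08,
                              arc_threshold = 0.5) {
  if (is.null(summary$mean_peak_nm) || is.null(pitch$half_pitch_nm)) {
    stop("summary and pitch estimate must be non-empty")
  }
  if (!nzchar(species)) species <- "unnamed_species"
  pred <- wavelength_to_half_pitch(summary$mean_peak_nm, oc)
  sd_pred <- propagate_sd(summary$sd_peak_nm %||% 0, oc)
  sd_obs <- pitch$sd_nm
  if (is.null(sd_obs) || is.na(sd_obs)) sd_obs <- 0
  arcs_present <- if (is.logical(arcs)) arcs else arcs >= arc_threshold
  row <- data.frame(
    species = species,
    mean_peak_nm = summary$mean_peak_nm,
    sd_peak_nm = summary$sd_peak_nm %||% 0,
    predicted_half_pitch_nm = as.numeric(pred),
    sd_predicted_nm = sd_pred,
    observed_half_pitch_nm = pitch$half_pitch_nm,
    sd_observed_nm = sd_obs,
    arcs_present = arcs_present,
    agreement = assess_agreement(pred, pitch$half_pitch_nm, sd_pred, sd_obs,
                                 rel_tol)
  )
  class(row) <- c("concordance_row", class(row))
  row
}

#' Four-step photonic-helicoid verdict
#'
#' The diagnostic requires (1) wavelength-selective circularly polarized
#' reflection of one handedness, (2) nested arcs in oblique section,
#' (3) a measured lamellar pitch, and (4) concordance between the reflected
#' peak and the pitch via `lambda = n_m * p`. `overall` is `"confirmed"`
#' only when all four hold, `"not_supported"` when any step fails, and
#' `"partial"` when no step fails but some are unavailable (`NA`).
#' Handedness is read from the dominant reflected channel when step 1 holds
#' (a helicoid reflects its own handedness).
#'
#' @param summary A `"panel_summary"` (uses `prop_selective`,
#'   `dominant_channel`), or `NA` if unavailable.
#' @param pitch A `"pitch_estimate"` or `NA`.
#' @param arcs Logical (or `NA`).
#' @param agreement Logical (or `NA`).
#' @param selective_frac Minimum fraction of selective cells for step 1
#'   (default 0.5).
#' @return Object of class `"diagnostic_verdict"`: the four step logicals,
#'   `overall`, `handedness`.
#' @export
four_step_verdict <- function(summary, pitch, arcs, agreement,
                              selective_frac = 0.5) {
  step1 <- if (is.list(summary) && !is.null(summary$prop_selective)) {
    summary$prop_selective >= selective_frac
  } else NA
  step2 <- if (length(arcs) == 1 && is.logical(arcs)) arcs else NA
  step3 <- if (is.list(pitch) && !is.null(pitch$half_pitch_nm)) {
    is.finite(pitch$half_pitch_nm) && pitch$half_pitch_nm > 0
  } else NA
  step4 <- if (length(agreement) == 1 && is.logical(agreement)) agreement
           else NA

  steps <- c(step1_cp_selective = step1, step2_arcs = step2,
             step3_pitch_measured = step3, step4_concordant = step4)
  overall <- if (any(steps %in% FALSE)) "not_supported"
             else if (all(steps %in% TRUE)) "confirmed"
             else "partial"
  handedness <- if (isTRUE(step1) && !is.null(summary$dominant_channel) &&
                    !is.na(summary$dominant_channel)) {
    if (summary$dominant_channel == "LCP") "left" else "right"
  } else "undetermined"
  structure(
    c(as.list(steps), list(overall = overall, handedness = handedness)),
    class = "diagnostic_verdict"
  )
}

#' @export
print.diagnostic_verdict <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "unavailable" else if (v) "yes" else "no"
  cat("photonic helicoid diagnostic\n",
      "  1. CP-selective reflection: ", fmt(x$step1_cp_selective), "\n",
      "  2. nested arcs:             ", fmt(x$step2_arcs), "\n",
      "  3. pitch measured:          ", fmt(x$step3_pitch_measured), "\n",
      "  4. structure-colour match:  ", fmt(x$step4_concordant), "\n",
      "  overall: ", x$overall, " (handedness ", x$handedness, ")\n",
      sep = "")
  invisible(x)
}

#' Render concordance rows as a display table
#'
#' Formats rows the way the species table is printed: integer-nm values
#' (round half to even) with "+/-" SDs and a check mark for arc presence.
#' The unrounded values are attached as the `"raw"` attribute (and written
#' to `raw_path` when given).
#'
#' @param rows Data frame of concordance rows ([build_concordance()]).
#' @param path Optional file for the display table (tab-delimited UTF-8).
#' @param raw_path Optional file for the machine-readable raw values (CSV).
#' @return Character vector of display lines, `"raw"` attribute carrying the
#'   raw data frame.
#' @export
render_table <- function(rows, path = NULL, raw_path = NULL) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1)
  disp <- sprintf(
    "%s\t%.0f ± %.0f\t%.0f ± %.0f\t%.0f ± %.0f\t%s",
    rows$species,
    round(rows$mean_peak_nm), round(rows$sd_peak_nm),
    round(rows$predicted_half_pitch_nm), round(rows$sd_predicted_nm),
    round(rows$observed_half_pitch_nm), round(rows$sd_observed_nm),
    ifelse(rows$arcs_present, "✓", "✗")
  )
  header <- paste("Species", "Mean peak reflectance (nm)",
                  "½ Pitch predicted (nm)", "½ Pitch observed (nm)",
                  "Arcs present", sep = "\t")
  lines <- c(header, disp)
  if (!is.null(path)) writeLines(lines, path, useBytes = FALSE)
  if (!is.null(raw_path)) {
    utils::write.csv(rows, raw_path, row.names = FALSE, quote = FALSE)
  }
  attr(lines, "raw") <- rows
  lines
}

#' Printed species table shipped with the package
#'
#' The published 20-species record: per-species mean peak reflectance
#' (+/- SD), predicted half-pitch, observed half-pitch (+/- SD), and arc
#' presence. Used to check that the optics chain reproduces the printed
#' predicted column from the printed mean-peak column.
#'
#' @return Data frame with columns `species`, `mean_peak_nm`, `sd_peak_nm`,
#'   `pred_half_pitch_nm`, `sd_pred_nm`, `obs_half_pitch_nm`, `sd_obs_nm`,
#'   `arcs_present`.
#' @export
species_table <- function() {
  path <- system.file("extdata", "species_table.tsv", package = "helicoidr")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
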