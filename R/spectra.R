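#' Normalize a raw spectrum against white and dark references
#'
#' Standard reflectance normalization against a white diffuser:
#' `R = (raw - dark) / (white - dark)`, elementwise on a shared grid.
#'
#' @param raw,white,dark `"spectrum"` objects on the same wavelength grid.
#' @return A `"spectrum"` with normalized reflectance.
#' @export
normalize_to_reference <- function(raw, white, dark) {
  for (s in list(raw, white, dark)) stopifnot(inherits(s, "spectrum"))
  if (!isTRUE(all.equal(raw$wavelength_nm, white$wavelength_nm)) ||
      !isTRUE(all.equal(raw$wavelength_nm, dark$wavelength_nm))) {
    stop("raw, white and dark spectra must share one wavelength grid; ",
         "resample first")
  }
  denom <- white$reflectance - dark$reflectance
  if (any(denom <= 0)) {
    stop(sprintf("white <= dark at %g nm: reference unusable there",
                 raw$wavelength_nm[which(denom <= 0)[1]]))
  }
  out <- raw
  out$reflectance <- (raw$reflectance - dark$reflectance) / denom
  out
}

#' Resample both channels of a pair onto a common uniform grid
#'
#' Linear interpolation of LCP and RCP onto `seq(lo, hi, by = step_nm)`
#' covering the overlap of the two wavelength ranges.
#'
#' @param pair A `"cell_spectrum_pair"`.
#' @param step_nm Grid step in nm.
#' @return The pair on the shared grid, `common_grid = TRUE`.
#' @export
resample_to_common_grid <- function(pair, step_nm = 1) {
  stopifnot(inherits(pair, "cell_spectrum_pair"))
  lo <- max(min(pair$lcp$wavelength_nm), min(pair$rcp$wavelength_nm))
  hi <- min(max(pair$lcp$wavelength_nm), max(pair$rcp$wavelength_nm))
  if (hi - lo < step_nm) {
    stop("LCP and RCP wavelength ranges are disjoint or overlap by less ",
         "than one grid step")
  }
  grid <- seq(lo, hi, by = step_nm)
  interp <- function(s) {
    s$reflectance <- stats::approx(s$wavelength_nm, s$reflectance,
                                   xout = grid)$y
    s$wavelength_nm <- grid
    s
  }
  pair$lcp <- interp(pair$lcp)
  pair$rcp <- interp(pair$rcp)
  pair$common_grid <- TRUE
  pair
}

# moving average with edge replication; window forced odd
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[
    (h + 1):(h + length(x))]
}

#' Locate the reflectance peak of one spectrum
#'
#' Smooths with a centered moving average (odd window), takes the global
#' maximum of the smoothed curve within the analysis range, and reports its
#' prominence: peak height minus the larger of the two minima flanking it
#' (towards each range boundary). Ties break to the lowest wavelength. A flat
#' spectrum has no defined peak (`is_defined = FALSE`, prominence 0).
#'
#' @param s A `"spectrum"`.
#' @param analysis_range Wavelength window, nm; default the visible
#'   400-800 nm band in which leaf reflectance peaks are scored.
#' @param smooth_window Moving-average window, samples (odd; default 5).
#' @return List: `peak_wavelength_nm`, `peak_reflectance`, `prominence`,
#'   `is_defined`.
#' @export
find_peak <- function(s, analysis_range = c(400, 800), smooth_window = 5) {
  stopifnot(inherits(s, "spectrum"))
  sel <- s$wavelength_nm >= analysis_range[1] &
    s$wavelength_nm <= analysis_range[2]
  if (sum(sel) < 5) {
    stop("fewer than 5 samples inside the analysis range")
  }
  w <- s$wavelength_nm[sel]
  sm <- moving_average(s$reflectance[sel], smooth_window)
  idx <- which.max(sm) # first maximum = lowest wavelength on ties
  # prominence against the deeper descent on each side; a peak sitting on a
  # range boundary is scored against its interior side only
  left_min <- if (idx > 1) min(sm[seq_len(idx - 1)]) else NA_real_
  right_min <- if (idx < length(sm)) min(sm[(idx + 1):length(sm)]) else NA_real_
  ref <- max(left_min, right_min, na.rm = TRUE)
  prom <- if (is.finite(ref)) sm[idx] - ref else 0
  if (prom <= 0 || !is.finite(prom)) {
    return(list(peak_wavelength_nm = NA_real_, peak_reflectance = sm[idx],
                prominence = 0, is_defined = FALSE))
  }
  list(peak_wavelength_nm = w[idx], peak_reflectance = sm[idx],
       prominence = prom, is_defined = TRUE)
}

#' Circular-polarization selectivity of a spectrum pair at a wavelength
#'
#' Averages each channel over `[lambda - w/2, lambda + w/2]` and reports the
#' dominant/other ratio, the degree of circular polarization
#' `DOCP = (L - R)/(L + R)`, and a selectivity call: dominant ratio at least
#' `ratio_threshold` and the dominant channel's peak prominence at least
#' `prominence_frac` of its peak height. Wavelength-selective reflection of
#' one circular handedness is the first of the four diagnostic criteria for
#' a photonic helicoid.
#'
#' @param pair A `"cell_spectrum_pair"` on a common grid.
#' @param lambda Evaluation wavelength, nm.
#' @param window_nm Averaging window width, nm (>= grid step).
#' @param ratio_threshold Selectivity ratio threshold (default 2).
#' @param prominence_frac Minimum relative prominence (default 0.05).
#' @return List: `selectivity_ratio`, `docp`, `dominant_channel`,
#'   `is_selective`, `flags`.
#' @export
cp_selectivity <- function(pair, lambda, window_nm = 20,
                           ratio_threshold = 2, prominence_frac = 0.05) {
  stopifnot(inherits(pair, "cell_spectrum_pair"))
  grid <- pair$lcp$wavelength_nm
  if (lambda < min(grid) || lambda > max(grid)) {
    stop("lambda outside the spectra's wavelength range")
  }
  sel <- abs(grid - lambda) <= window_nm / 2
  if (!any(sel)) sel <- which.min(abs(grid - lambda))
  L <- mean(pair$lcp$reflectance[sel])
  R <- mean(pair$rcp$reflectance[sel])

  flags <- character()
  eps <- 1e-9
  dominant <- if (L >= R) "LCP" else "RCP"
  dom <- max(L, R); oth <- min(L, R)
  if (oth < eps) {
    oth <- eps
    flags <- c(flags, "denominator_floored")
  }
  ratio <- dom / oth
  docp <- if (L + R > 0) (L - R) / (L + R) else {
    flags <- c(flags, "zero_total")
    0
  }
  dom_spec <- if (dominant == "LCP") pair$lcp else pair$rcp
  pk <- find_peak(dom_spec)
  is_selective <- ratio >= ratio_threshold &&
    pk$is_defined && pk$prominence >= prominence_frac * pk$peak_reflectance
  list(selectivity_ratio = ratio, docp = docp, dominant_channel = dominant,
       is_selective = is_selective, flags = flags)
}

#' Colour bin of a peak wavelength
#'
#' Half-open visible bins: violet [400, 450) nm, blue [450, 500) nm, green
#' [500, 570) nm, long [570, 800] nm. Boundary wavelengths go to the upper
#' bin.
#'
#' @param lambda Wavelength(s) in nm, within [400, 800].
#' @return Character vector of bin names.
#' @examples
#' classify_colour_bin(478) # "blue"
#' @export
classify_colour_bin <- function(lambda) {
  if (any(lambda < 400 | lambda > 800)) {
    stop("wavelength outside the 400-800 nm analysis range")
  }
  bin <- character(length(lambda))
  bin[lambda < 450] <- "violet"
  bin[lambda >= 450 & lambda < 500] <- "blue"
  bin[lambda >= 500 & lambda < 570] <- "green"
  bin[lambda >= 570] <- "long"
  bin
}

#' Analyze one spectrum pair into a per-cell result row
#'
#' Runs [find_peak()] on both channels, scores CP selectivity at the
#' dominant peak, and bins the colour.
#'
#' @inheritParams cp_selectivity
#' @param analysis_range,smooth_window Passed to [find_peak()].
#' @return One-row data frame: cell_id, peak_wavelength_nm,
#'   peak_reflectance, prominence, selectivity_ratio, docp, colour_bin,
#'   dominant_channel, is_selective, is_defined.
#' @export
analyze_pair <- function(pair, analysis_range = c(400, 800),
                         smooth_window = 5, window_nm = 20,
                         ratio_threshold = 2, prominence_frac = 0.05) {
  stopifnot(inherits(pair, "cell_spectrum_pair"))
  if (!isTRUE(pair$common_grid)) pair <- resample_to_common_grid(pair)
  pk_l <- find_peak(pair$lcp, analysis_range, smooth_window)
  pk_r <- find_peak(pair$rcp, analysis_range, smooth_window)
  pk <- if ((pk_l$prominence %||% 0) >= (pk_r$prominence %||% 0)) pk_l else pk_r
  if (!pk$is_defined) {
    return(data.frame(
      cell_id = pair$cell_id, peak_wavelength_nm = NA_real_,
      peak_reflectance = pk$peak_reflectance, prominence = 0,
      selectivity_ratio = NA_real_, docp = NA_real_,
      colour_bin = NA_character_, dominant_channel = NA_character_,
      is_selective = FALSE, is_defined = FALSE
    ))
  }
  cp <- cp_selectivity(pair, pk$peak_wavelength_nm, window_nm,
                       ratio_threshold, prominence_frac)
  data.frame(
    cell_id = pair$cell_id,
    peak_wavelength_nm = pk$peak_wavelength_nm,
    peak_reflectance = pk$peak_reflectance,
    prominence = pk$prominence,
    selectivity_ratio = cp$selectivity_ratio,
    docp = cp$docp,
    colour_bin = classify_colour_bin(pk$peak_wavelength_nm),
    dominant_channel = cp$dominant_channel,
    is_selective = cp$is_selective,
    is_defined = TRUE
  )
}

#' Summarize per-cell peak results into a species panel summary
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the defined per-cell
#' peak wavelengths, the per-species statistic reported alongside pitch
#' measurements.
#'
#' @param results Data frame of per-cell rows from [analyze_pair()].
#' @return List of class `"panel_summary"`: `mean_peak_nm`, `sd_peak_nm`,
#'   `n_cells`, `prop_selective`, `dominant_channel`, `per_cell`, `flags`.
#' @examples
#' summarize_cells(data.frame(peak_wavelength_nm = c(470, 480, 490),
#'                            is_defined = TRUE, is_selective = TRUE,
#'                            dominant_channel = "LCP"))
#' @export
summarize_cells <- function(results) {
  stopifnot(is.data.frame(results))
  ok <- results[isTRUE_vec(results$is_defined), , drop = FALSE]
  if (nrow(ok) == 0) stop("no cell has a defined reflectance peak")
  peaks <- ok$peak_wavelength_nm
  flags <- character()
  if (nrow(ok) == 1) flags <- c(flags, "n1_sd_zero")
  dom <- if (!is.null(ok$dominant_channel)) {
    tab <- table(ok$dominant_channel)
    names(tab)[which.max(tab)]
  } else NA_character_
  structure(
    list(
      mean_peak_nm = mean(peaks),
      sd_peak_nm = if (length(peaks) > 1) stats::sd(peaks) else 0,
      n_cells = nrow(ok),
      prop_selective = if (!is.null(ok$is_selective)) mean(ok$is_selective)
                       else NA_real_,
      dominant_channel = dom,
      per_cell = ok,
      flags = flags
    ),
    class = "panel_summary"
  )
}

isTRUE_vec <- function(x) if (is.null(x)) TRUE else x %in% TRUE
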