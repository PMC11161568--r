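#' Simulate a paired LCP/RCP reflectance spectrum for one epidermal cell
#'
#' The matched-handedness channel carries a single chiral reflection band:
#' centre `lambda_c = n_mean * pitch_nm`, full width at half maximum
#' `delta_n * pitch_nm`, and saturating amplitude
#' `tanh(n_turns * pi * delta_n / (2 * n_mean))^2` (coupled-wave form, so
#' few-turn walls give weak bands and ~70-turn walls reflect near unity).
#' The band is a Gaussian bump on top of `baseline`; the opposite channel is
#' baseline only. Independent seeded Gaussian noise is added to both channels
#' and reflectance is clipped to [0, 1].
#'
#' @param params A [helicoid_params()] object.
#' @param grid Ascending wavelength grid in nm, within [350, 900].
#' @param baseline Baseline (non-selective) reflectance level.
#' @param noise_sd Additive Gaussian noise SD, reflectance units (>= 0).
#' @param seed Integer seed for the noise.
#' @param cell_id Identifier attached to both channels.
#'
#' @return An object of class `"cell_spectrum_pair"`: list with `lcp`, `rcp`
#'   (each a `"spectrum"`), `cell_id`, `common_grid = TRUE` and a character
#'   vector `flags` (contains `"peak_outside_grid"` when `lambda_c` falls
#'   outside `grid`, in which case a warning is also raised).
#' @examples
#' hp <- helicoid_params(320, "left", n_turns = 70)
#' pair <- simulate_cp_spectrum(hp, noise_sd = 0, seed = 1)
#' pair$lcp$wavelength_nm[which.max(pair$lcp$reflectance)] # 480 nm
#' @export
simulate_cp_spectrum <- function(params,
                                 grid = seq(350, 900, by = 1),
                                 baseline = 0.05,
                                 noise_sd = 0.01,
                                 seed = 1L,
                                 cell_id = "cell") {
  stopifnot(inherits(params, "helicoid_params"))
  if (any(diff(grid) <= 0)) stop("wavelength grid must be strictly ascending")
  if (min(grid) < 350 || max(grid) > 900) {
    stop("wavelength grid must lie within [350, 900] nm")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  lambda_c <- params$n_mean * params$pitch_nm
  fwhm <- params$delta_n * params$pitch_nm
  amp <- tanh(params$n_turns * pi * params$delta_n / (2 * params$n_mean))^2

  flags <- character()
  if (lambda_c < min(grid) || lambda_c > max(grid)) {
    warning(sprintf(
      "band centre %.1f nm lies outside the wavelength grid [%g, %g]",
      lambda_c, min(grid), max(grid)
    ))
    flags <- c(flags, "peak_outside_grid")
  }

  if (fwhm > 0) {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    band <- amp * exp(-((grid - lambda_c)^2) / (2 * sigma^2))
  } else {
    band <- numeric(length(grid)) # zero birefringence: no band at all
  }
  matched <- baseline + band
  opposite <- rep(baseline, length(grid))

  noise <- withr::with_seed(as.integer(seed), {
    matrix(stats::rnorm(2 * length(grid), sd = noise_sd), ncol = 2)
  })
  matched <- pmin(pmax(matched + noise[, 1], 0), 1)
  opposite <- pmin(pmax(opposite + noise[, 2], 0), 1)

  ch <- matched_channel(params)
  mk <- function(refl, channel) {
    structure(
      list(
        wavelength_nm = as.numeric(grid), reflectance = refl,
        channel = channel, cell_id = cell_id
      ),
      class = "spectrum"
    )
  }
  spectra <- if (ch == "LCP") {
    list(lcp = mk(matched, "LCP"), rcp = mk(opposite, "RCP"))
  } else {
    list(lcp = mk(opposite, "LCP"), rcp = mk(matched, "RCP"))
  }
  structure(
    c(spectra, list(cell_id = cell_id, common_grid = TRUE, flags = flags)),
    class = "cell_spectrum_pair"
  )
}

#' Simulate a ten-cell species panel with per-cell pitch variability
#'
#' Emulates the study design of measuring ten adaxial epidermal cells per
#' species. Each cell's pitch is drawn from a normal law with mean
#' `params$pitch_nm` and SD `pitch_cv * pitch_nm` (truncated positive), then
#' a spectrum pair and a transverse band image are generated for that cell.
#' One oblique-section arc image at the species mean pitch is attached. All
#' per-cell seeds derive deterministically from `seed`, so the same call
#' regenerates an identical panel.
#'
#' @param params [helicoid_params()] giving the species-level ground truth.
#' @param n_cells Cells per panel (>= 1); the study protocol used 10.
#' @param pitch_cv Coefficient of variation of per-cell pitch, in [0, 0.3).
#' @param seed Master integer seed.
#' @param grid,baseline,noise_sd Passed to [simulate_cp_spectrum()].
#' @param nm_per_px,image_shape,image_noise_sd Passed to
#'   [simulate_band_image()].
#' @param cut_angle_deg Obliquity of the panel's arc image, degrees.
#'
#' @return Object of class `"species_panel"`: list with `cells` (each a list
#'   of `pitch_nm`, `pair`, `band_image`), `arc_image`, `params`, `pitch_cv`,
#'   `seed`.
#' @export
simulate_species_panel <- function(params, n_cells = 10, pitch_cv = 0.05,
                                   seed = 1L,
                                   grid = seq(350, 900, by = 1),
                                   baseline = 0.05, noise_sd = 0.01,
                                   nm_per_px = 2, image_shape = c(256, 1024),
                                   image_noise_sd = 0.02,
                                   cut_angle_deg = 30) {
  stopifnot(inherits(params, "helicoid_params"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (pitch_cv < 0 || pitch_cv >= 0.3) stop("pitch_cv must be in [0, 0.3)")
  seed <- as.integer(seed)

  pitches <- withr::with_seed(seed, {
    p <- stats::rnorm(n_cells, params$pitch_nm, pitch_cv * params$pitch_nm)
    while (any(p <= 0)) { # cv < 0.3 makes this astronomically rare
      p[p <= 0] <- stats::rnorm(sum(p <= 0), params$pitch_nm,
                                pitch_cv * params$pitch_nm)
    }
    p
  })

  cells <- lapply(seq_len(n_cells), function(i) {
    cp <- helicoid_params(pitches[i], params$handedness, params$n_turns,
                          params$n_ordinary, params$n_extraordinary)
    id <- sprintf("cell_%02d", i)
    list(
      pitch_nm = pitches[i],
      pair = simulate_cp_spectrum(cp, grid, baseline, noise_sd,
                                  seed = derive_seed(seed, 1000L + i),
                                  cell_id = id),
      band_image = simulate_band_image(cp, nm_per_px = nm_per_px,
                                       shape = image_shape,
                                       noise_sd = image_noise_sd,
                                       seed = derive_seed(seed, 2000L + i))
    )
  })
  arc <- simulate_arc_image(params, cut_angle_deg = cut_angle_deg,
                            nm_per_px = nm_per_px, shape = image_shape,
                            seed = derive_seed(seed, 3000L))
  structure(
    list(cells = cells, arc_image = arc, params = params,
         pitch_cv = pitch_cv, seed = seed),
    class = "species_panel"
  )
}

# stable per-component seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483647)
}
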