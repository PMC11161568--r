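#' Simulate a transverse-section TEM band image
#'
#' In transverse section a helicoidal wall shows alternating electron-dense
#' and electron-opaque bands whose repeat is the half-pitch `p/2` (fibril
#' orientations 180 degrees apart look identical). Intensity varies
#' sinusoidally along the image x axis (columns) with apparent spatial period
#' `(pitch_nm/2) / cos(tilt_deg)`: sectioning at an angle to the true
#' transverse plane stretches the apparent spacing. The true half-pitch is
#' recorded in the metadata.
#'
#' @param params [helicoid_params()].
#' @param nm_per_px Image scale, nm per pixel (> 0).
#' @param shape Image dimensions `c(rows, cols)` in pixels.
#' @param tilt_deg Section tilt from the true transverse plane, degrees in
#'   [0, 85).
#' @param contrast Peak-to-peak band contrast, intensity units in (0, 1].
#' @param noise_sd Additive Gaussian noise SD, intensity units.
#' @param seed Integer seed for the noise.
#'
#' @return Object of class `"band_image"`: list with `intensity` (matrix in
#'   [0, 1], rows = y, cols = x), `nm_per_px`, `tilt_deg`, and `metadata`
#'   (`true_half_pitch_nm`, `apparent_period_nm`, ...).
#' @examples
#' img <- simulate_band_image(helicoid_params(320, "left"), nm_per_px = 2)
#' img$metadata$apparent_period_nm / img$nm_per_px # 80 px band period
#' @export
simulate_band_image <- function(params, nm_per_px = 2, shape = c(256, 1024),
                                tilt_deg = 0, contrast = 0.5,
                                noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(params, "helicoid_params"))
  if (nm_per_px <= 0) stop("nm_per_px must be > 0")
  if (tilt_deg < 0 || tilt_deg >= 85) {
    stop("tilt_deg must be in [0, 85): apparent period diverges beyond")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  half_pitch <- params$pitch_nm / 2
  apparent <- half_pitch / cos(tilt_deg * pi / 180)

  nr <- shape[1]; nc <- shape[2]
  x_nm <- (seq_len(nc) - 1) * nm_per_px
  row_profile <- 0.5 + (contrast / 2) * sin(2 * pi * x_nm / apparent)
  intensity <- matrix(row_profile, nrow = nr, ncol = nc, byrow = TRUE)
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed), {
      matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
    })
    intensity <- intensity + noise
  }
  intensity <- pmin(pmax(intensity, 0), 1)

  structure(
    list(
      intensity = intensity, nm_per_px = nm_per_px, tilt_deg = tilt_deg,
      metadata = list(
        true_half_pitch_nm = half_pitch,
        apparent_period_nm = apparent,
        handedness = params$handedness,
        kind = "band"
      )
    ),
    class = "band_image"
  )
}

#' Simulate an oblique-section arc (Bouligand) image
#'
#' Oblique sections through a helicoid show nested arcs: the in-plane fibril
#' orientation rotates as `phi(z) = +/- 2*pi*z / pitch_nm` (sign from
#' handedness) through wall depth `z`, and an oblique cut maps depth onto one
#' image axis, `z = y_nm * sin(cut_angle_deg)`. The texture is rendered by
#' stamping short fibril segments (anisotropic Gaussian stamps) whose
#' orientation follows `phi` at their depth; stamp centres are placed in
#' mirror pairs about the vertical midline so that chirality acts as a pure
#' reflection: the left-handed image equals the horizontally flipped
#' right-handed image at the same seed. The arc repeat along the cut is
#' `(pitch_nm/2) / sin(cut_angle_deg)` (recorded in metadata).
#'
#' @param params [helicoid_params()].
#' @param cut_angle_deg Cut obliquity from the layer plane, degrees in
#'   [5, 85].
#' @param segment_density Fibril segments stamped per 32x32 px tile.
#' @param nm_per_px Image scale, nm per pixel (> 0).
#' @param shape Image dimensions `c(rows, cols)`.
#' @param seed Integer seed for segment placement.
#' @param noise_sd Optional additive noise SD (default 0).
#'
#' @return A `"band_image"` whose metadata carries `arc_repeat_nm` and
#'   `kind = "arc"`.
#' @export
simulate_arc_image <- function(params, cut_angle_deg = 30,
                               segment_density = 6, nm_per_px = 2,
                               shape = c(256, 256), seed = 1L,
                               noise_sd = 0) {
  stopifnot(inherits(params, "helicoid_params"))
  if (cut_angle_deg < 5 || cut_angle_deg > 85) {
    stop("cut_angle_deg must be in [5, 85]")
  }
  if (nm_per_px <= 0) stop("nm_per_px must be > 0")
  nr <- shape[1]; nc <- shape[2]
  sin_a <- sin(cut_angle_deg * pi / 180)
  sgn <- if (params$handedness == "right") 1 else -1

  n_seg <- ceiling(segment_density * nr * nc / (32 * 32))
  seg <- withr::with_seed(as.integer(seed), {
    data.frame(
      # x centred on the midline so the mirror pair of x is exactly -x
      x = stats::runif(n_seg, -nc / 2, nc / 2),
      y = stats::runif(n_seg, 1, nr)
    )
  })
  # mirror pairing: every stamp at (x, y) has a partner at (-x, y)
  seg <- rbind(seg, data.frame(x = -seg$x, y = seg$y))

  # fibril orientation at image row y (depth z advances with the cut)
  phi_of_y <- function(y) sgn * 2 * pi * (y * nm_per_px * sin_a) / params$pitch_nm

  sigma_a <- 4   # stamp half-length along the fibril, px
  sigma_b <- 1.2 # stamp half-width across it, px
  half_w <- ceiling(3 * sigma_a)
  intensity <- matrix(0, nr, nc)
  xc_of_col <- function(j) j - (nc + 1) / 2 # centred column coordinate

  for (k in seq_len(nrow(seg))) {
    phi <- phi_of_y(seg$y[k])
    cphi <- cos(phi); sphi <- sin(phi)
    j0 <- seg$x[k] + (nc + 1) / 2
    i0 <- seg$y[k]
    jj <- max(1, floor(j0 - half_w)):min(nc, ceiling(j0 + half_w))
    ii <- max(1, floor(i0 - half_w)):min(nr, ceiling(i0 + half_w))
    if (!length(jj) || !length(ii)) next
    dx <- outer(rep(1, length(ii)), xc_of_col(jj) - xc_of_col(j0))
    dy <- outer(ii - i0, rep(1, length(jj)))
    a <- dx * cphi + dy * sphi
    b <- -dx * sphi + dy * cphi
    intensity[ii, jj] <- intensity[ii, jj] +
      exp(-(a^2 / (2 * sigma_a^2) + b^2 / (2 * sigma_b^2)))
  }
  if (max(intensity) > 0) intensity <- intensity / max(intensity)
  if (noise_sd > 0) {
    noise <- withr::with_seed(derive_seed(as.integer(seed), 17L), {
      matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
    })
    intensity <- pmin(pmax(intensity + noise, 0), 1)
  }

  structure(
    list(
      intensity = intensity, nm_per_px = nm_per_px, tilt_deg = NA_real_,
      metadata = list(
        true_half_pitch_nm = params$pitch_nm / 2,
        arc_repeat_nm = (params$pitch_nm / 2) / sin_a,
        cut_angle_deg = cut_angle_deg,
        handedness = params$handedness,
        kind = "arc"
      )
    ),
    class = "band_image"
  )
}

#' Simulate a structureless noise image
#'
#' Uniform-noise control with the same container as [simulate_band_image()];
#' used as the negative reference when validating arc scoring and
#' orientation estimation.
#'
#' @param shape Image dimensions `c(rows, cols)`.
#' @param nm_per_px Image scale, nm per pixel.
#' @param seed Integer seed.
#' @return A `"band_image"` with `kind = "noise"` metadata.
#' @export
simulate_noise_image <- function(shape = c(256, 256), nm_per_px = 2,
                                 seed = 1L) {
  intensity <- withr::with_seed(as.integer(seed), {
    matrix(stats::runif(shape[1] * shape[2]), shape[1], shape[2])
  })
  structure(
    list(intensity = intensity, nm_per_px = nm_per_px, tilt_deg = NA_real_,
         metadata = list(kind = "noise")),
    class = "band_image"
  )
}
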