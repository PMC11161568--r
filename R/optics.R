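#' Optical constants of the cell wall
#'
#' Carries the mean refractive index `n_mean = (n_o + n_e)/2` of the
#' birefringent wall material. The accepted value for resin-embedded plant
#' cell walls is 1.50 (water-hydrated walls would sit nearer 1.3-1.4, so the
#' constant is configurable).
#'
#' @param n_mean Mean refractive index (> 1), default 1.50.
#' @return Object of class `"optical_constants"`.
#' @export
optical_constants <- function(n_mean = 1.50) {
  stopifnot(is.numeric(n_mean), length(n_mean) == 1)
  if (n_mean <= 1) stop("n_mean must exceed 1")
  structure(list(n_mean = as.numeric(n_mean)), class = "optical_constants")
}

#' Reflected wavelength of a helicoid at normal incidence
#'
#' `lambda = n_mean * p`: a helicoid of pitch `p` selectively reflects
#' circularly polarized light of wavelength `n_mean * p` at normal
#' incidence.
#'
#' @param pitch_nm Full helicoid pitch, nm (> 0).
#' @param oc [optical_constants()].
#' @return Wavelength in nm, exact arithmetic.
#' @examples
#' pitch_to_wavelength(320) # 480
#' @export
pitch_to_wavelength <- function(pitch_nm, oc = optical_constants()) {
  if (any(pitch_nm <= 0)) stop("pitch_nm must be > 0")
  oc$n_mean * pitch_nm
}

#' Half-pitch predicted from a reflectance peak wavelength
#'
#' Inverts the structure-colour relation to the quantity measured on TEM
#' band images: `half-pitch = lambda / (2 * n_mean)`. The raw value is always
#' returned; with `report_rounding = TRUE` a `display` attribute carries the
#' integer-nm table value (round half to even).
#'
#' @param lambda Peak wavelength(s), nm (> 0).
#' @param oc [optical_constants()].
#' @param report_rounding Attach rounded display values?
#' @return Half-pitch in nm (numeric; `display` attribute when requested).
#' @examples
#' wavelength_to_half_pitch(482, report_rounding = TRUE) # 160.67, display 161
#' @export
wavelength_to_half_pitch <- function(lambda, oc = optical_constants(),
                                     report_rounding = FALSE) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  hp <- lambda / (2 * oc$n_mean)
  if (report_rounding) attr(hp, "display") <- round(hp)
  hp
}

#' Propagate a peak-wavelength SD to the half-pitch scale
#'
#' Division by the constant `2 * n_mean` scales an SD linearly:
#' `sd_halfpitch = sd_lambda / (2 * n_mean)`.
#'
#' @param sd_lambda SD of the peak wavelength, nm (>= 0).
#' @param oc [optical_constants()].
#' @return SD of the predicted half-pitch, nm.
#' @examples
#' propagate_sd(27) # 9
#' @export
propagate_sd <- function(sd_lambda, oc = optical_constants()) {
  if (any(sd_lambda < 0)) stop("sd_lambda must be >= 0")
  sd_lambda / (2 * oc$n_mean)
}
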