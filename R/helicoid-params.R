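#' Ground-truth description of a helicoidal cell wall
#'
#' A helicoidal (Bouligand) wall is a stack of cellulose layers whose fibril
#' orientation rotates by a small fixed angle per layer. The pitch `p` is the
#' stacking distance over one full 360 degree rotation; in transverse TEM
#' section the visible banding repeat is `p/2`, because fibril orientations
#' 180 degrees apart are indistinguishable. The wall material is birefringent:
#' `n_mean = (n_o + n_e)/2` links pitch to the reflected wavelength via
#' `lambda = n_mean * p` at normal incidence, and the birefringence
#' `delta_n = n_e - n_o` sets the chiral reflection bandwidth (~ `delta_n * p`).
#'
#' @param pitch_nm Full helicoid pitch in nm (> 0). One 360 degree fibril
#'   rotation.
#' @param handedness `"left"` or `"right"`. A helicoid reflects circularly
#'   polarized light of its own handedness only.
#' @param n_turns Number of full helicoids in the stack (>= 1). Observed
#'   range in leaf epidermes runs from ~5 in weakly coloured species to ~70
#'   in the thickest-walled ones.
#' @param n_ordinary,n_extraordinary Ordinary and extraordinary refractive
#'   indices of the wall (`n_extraordinary >= n_ordinary > 1`). Defaults give
#'   `n_mean = 1.50` (the accepted cell-wall value) with `delta_n = 0.05`.
#'
#' @return An object of class `"helicoid_params"`: a list with the validated
#'   fields plus derived `n_mean` and `delta_n`.
#' @examples
#' hp <- helicoid_params(320, "left", n_turns = 70)
#' hp$n_mean * hp$pitch_nm # predicted reflection peak, nm
#' @export
helicoid_params <- function(pitch_nm, handedness = c("left", "right"),
                            n_turns = 40,
                            n_ordinary = 1.475, n_extraordinary = 1.525) {
  handedness <- match.arg(handedness)
  stopifnot(is.numeric(pitch_nm), length(pitch_nm) == 1, is.finite(pitch_nm))
  if (pitch_nm <= 0) stop("pitch_nm must be > 0")
  if (n_turns < 1) stop("n_turns must be >= 1")
  if (!(n_ordinary > 1)) stop("n_ordinary must exceed 1")
  if (n_extraordinary < n_ordinary) {
    stop("n_extraordinary must be >= n_ordinary")
  }
  structure(
    list(
      pitch_nm = as.numeric(pitch_nm),
      handedness = handedness,
      n_turns = as.numeric(n_turns),
      n_ordinary = as.numeric(n_ordinary),
      n_extraordinary = as.numeric(n_extraordinary),
      n_mean = (n_ordinary + n_extraordinary) / 2,
      delta_n = n_extraordinary - n_ordinary
    ),
    class = "helicoid_params"
  )
}

#' @export
print.helicoid_params <- function(x, ...) {
  cat(sprintf(
    "helicoid: pitch %.1f nm, %s-handed, %g turns, n_o %.3f, n_e %.3f (n_mean %.3f)\n",
    x$pitch_nm, x$handedness, x$n_turns, x$n_ordinary, x$n_extraordinary,
    x$n_mean
  ))
  invisible(x)
}

# channel (LCP/RCP) that a helicoid of this handedness reflects
matched_channel <- function(params) {
  if (params$handedness == "left") "LCP" else "RCP"
}
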