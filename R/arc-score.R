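#' Score the nested-arc (Bouligand) signature of an oblique-section image
#'
#' In an oblique section through a helicoid the local fibril orientation
#' rotates quasi-linearly with position along the cut and wraps every
#' half-pitch, which is what produces the nested-arc texture. The image is
#' divided into overlapping horizontal strips; each strip's dominant local
#' orientation `theta_w` is estimated with a structure tensor and encoded as
#' the coherence-weighted phasor `c_w * exp(2i * theta_w)`. For ideal arcs
#' this sequence is a complex sinusoid in the strip index; the score is the
#' largest normalized spectral magnitude of the mean-subtracted sequence
#' over a fine frequency grid. Straight parallel bands (constant
#' orientation) and pure noise (incoherent orientation) both score near 0;
#' arc textures score near 1. Deterministic given the image.
#'
#' @param img A `"band_image"` of at least 64 x 64 px.
#' @param strip_height Strip height in px (default 16).
#' @param strip_step Strip spacing in px (default 8).
#' @param smooth_px Structure-tensor presmoothing scale, px (default 3).
#' @return Score in [0, 1].
#' @export
arc_score <- function(img, strip_height = 16, strip_step = 8,
                      smooth_px = 3) {
  stopifnot(inherits(img, "band_image"))
  intensity <- img$intensity
  nr <- nrow(intensity); nc <- ncol(intensity)
  if (nr < 64 || nc < 64) stop("image smaller than 64 x 64 px")
  intensity <- box_smooth(intensity, smooth_px)

  starts <- seq(1, nr - strip_height + 1, by = strip_step)
  v <- vapply(starts, function(s) {
    st <- structure_tensor(intensity, rows = s:(s + strip_height - 1))
    st$coherence * exp(2i * st$theta)
  }, complex(1))
  if (all(Mod(v) == 0)) stop("degenerate orientation field: no gradients")

  u <- v - mean(v)
  nw <- length(u)
  # orientation may rotate either way (sign follows handedness and image
  # orientation), so both frequency signs are probed
  omega <- seq(pi / nw, pi, length.out = 512)
  w_idx <- seq_len(nw)
  spec <- vapply(omega, function(om) {
    max(Mod(sum(u * exp(-1i * om * w_idx))),
        Mod(sum(u * exp(1i * om * w_idx))))
  }, numeric(1))
  min(max(spec) / nw, 1)
}
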