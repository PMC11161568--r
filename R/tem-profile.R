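# Structure-tensor machinery for lamellar orientation estimation.
# Gradients by central differences on the interior; the tensor is averaged
# over the region of interest, so the dominant orientation is the mean
# gradient direction (normal to the bands).

# separable box presmoothing (edge-replicated); suppresses pixel noise
# before gradients are taken
box_smooth <- function(intensity, w) {
  if (w <= 1) return(intensity)
  sm <- apply(intensity, 2, moving_average, window = w)
  t(apply(sm, 1, moving_average, window = w))
}

structure_tensor <- function(intensity, rows = NULL) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  if (is.null(rows)) rows <- 2:(nr - 1)
  rows <- rows[rows >= 2 & rows <= nr - 1]
  cols <- 2:(nc - 1)
  gx <- (intensity[rows, cols + 1] - intensity[rows, cols - 1]) / 2
  gy <- (intensity[rows + 1, cols] - intensity[rows - 1, cols]) / 2
  jxx <- sum(gx * gx); jyy <- sum(gy * gy); jxy <- sum(gx * gy)
  total <- jxx + jyy
  coherence <- if (total > 0) sqrt((jxx - jyy)^2 + 4 * jxy^2) / total else 0
  # dominant gradient direction, mod pi, in (-pi/2, pi/2]
  theta <- 0.5 * atan2(2 * jxy, jxx - jyy)
  list(theta = theta, coherence = coherence, energy = total)
}

#' Extract a 1-D band-normal intensity profile from a band image
#'
#' Estimates the lamellar orientation from the dominant gradient direction
#' (whole-image structure tensor), then averages intensity in 1-px bins of
#' the coordinate along the band normal. Equivalent to rotating the image so
#' the bands are vertical and taking column means, but without
#' interpolation. Images with no dominant orientation (coherence below
#' `min_coherence`) are rejected unless a manual `orientation_deg` override
#' is supplied.
#'
#' @param img A `"band_image"` of at least 32 x 32 px.
#' @param orientation_deg Optional manual band-normal direction, degrees
#'   (0 = along image x).
#' @param min_coherence Isotropy threshold in [0, 1] (default 0.2).
#' @param smooth_px Structure-tensor presmoothing scale, px (box filter;
#'   default 5). Orientation only; the profile itself is not smoothed.
#' @return List of class `"band_profile"`: `profile`, `nm_per_sample`,
#'   `orientation_deg`, `coherence`.
#' @export
extract_profile <- function(img, orientation_deg = NULL,
                            min_coherence = 0.2, smooth_px = 5) {
  stopifnot(inherits(img, "band_image"))
  intensity <- img$intensity
  if (nrow(intensity) < 32 || ncol(intensity) < 32) {
    stop("image smaller than 32 x 32 px")
  }
  st <- structure_tensor(box_smooth(intensity, smooth_px))
  if (is.null(orientation_deg)) {
    if (st$coherence < min_coherence) {
      stop("no dominant lamellar orientation (coherence ",
           sprintf("%.3f", st$coherence), " < ", min_coherence,
           "); pass orientation_deg to override")
    }
    theta <- st$theta
  } else {
    theta <- orientation_deg * pi / 180
  }
  # canonical direction in (-pi/2, pi/2] so the profile runs one way only
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi

  nr <- nrow(intensity); nc <- ncol(intensity)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  t_coord <- xs * cos(theta) + ys * sin(theta)
  bin <- round(t_coord - min(t_coord)) + 1L
  sums <- tapply(as.vector(intensity), as.vector(bin), sum)
  counts <- tabulate(as.vector(bin), nbins = max(bin))
  counts <- counts[counts > 0]
  prof <- as.numeric(sums) / counts
  # drop thin corner bins that average too few pixels to be reliable
  keep <- counts >= 0.5 * stats::median(counts)
  prof <- prof[keep]
  structure(
    list(profile = prof, nm_per_sample = img$nm_per_px,
         orientation_deg = theta * 180 / pi, coherence = st$coherence),
    class = "band_profile"
  )
}
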