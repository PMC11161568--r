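#' Read a two-column reflectance spectrum file
#'
#' Accepts comma-, tab- or whitespace-delimited text with two numeric columns
#' (wavelength nm, reflectance) and at most one optional header line. Rows
#' are sorted to ascending wavelength; duplicated wavelengths are an error.
#'
#' @param path File path.
#' @param channel `"LCP"` or `"RCP"`. If `NULL`, inferred from a `_LCP` /
#'   `_RCP` suffix in the file name.
#' @param cell_id Identifier; defaults to the file name stem.
#' @return A `"spectrum"` object.
#' @export
read_spectrum <- function(path, channel = NULL, cell_id = NULL) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty spectrum file: ", path)

  parse_row <- function(ln) {
    fields <- strsplit(ln, "[,\t ]+")[[1]]
    fields <- fields[nzchar(fields)]
    suppressWarnings(as.numeric(fields))
  }
  first <- parse_row(lines[1])
  if (any(is.na(first))) lines <- lines[-1] # one optional header line
  if (!length(lines)) stop("spectrum file has no data rows: ", path)

  rows <- lapply(lines, parse_row)
  bad <- vapply(rows, function(r) length(r) != 2 || any(is.na(r)), logical(1))
  if (any(bad)) {
    stop(sprintf("non-numeric or malformed row(s) in %s (e.g. line %d)",
                 path, which(bad)[1]))
  }
  m <- do.call(rbind, rows)
  o <- order(m[, 1])
  w <- m[o, 1]; r <- m[o, 2]
  if (anyDuplicated(w)) {
    stop(sprintf("duplicate wavelength %g nm in %s", w[which(duplicated(w))[1]],
                 path))
  }

  if (is.null(channel)) {
    stem <- tools::file_path_sans_ext(basename(path))
    channel <- if (grepl("_LCP$", stem, ignore.case = TRUE)) "LCP"
               else if (grepl("_RCP$", stem, ignore.case = TRUE)) "RCP"
               else stop("channel not given and not inferable from file name: ",
                         path)
  }
  channel <- match.arg(toupper(channel), c("LCP", "RCP"))
  if (is.null(cell_id)) {
    cell_id <- sub("_(LCP|RCP)$", "", tools::file_path_sans_ext(basename(path)),
                   ignore.case = TRUE)
  }
  structure(
    list(wavelength_nm = w, reflectance = r, channel = channel,
         cell_id = cell_id),
    class = "spectrum"
  )
}

#' Write a spectrum as two-column CSV
#'
#' @param s A `"spectrum"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  df <- data.frame(wavelength_nm = s$wavelength_nm,
                   reflectance = s$reflectance)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a band image as single-channel TIFF plus sidecar metadata
#'
#' The image goes to `path` (16-bit grayscale TIFF); scale and ground-truth
#' metadata go to a plain-text `<path>.meta` sidecar of `key = value` lines.
#'
#' @param img A `"band_image"`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_band_image <- function(img, path) {
  stopifnot(inherits(img, "band_image"))
  tiff::writeTIFF(img$intensity, path, bits.per.sample = 16)
  meta <- c(
    nm_per_px = img$nm_per_px,
    tilt_deg = img$tilt_deg,
    img$metadata
  )
  meta <- meta[!vapply(meta, function(v) length(v) != 1 || is.na(v), logical(1))]
  writeLines(sprintf("%s = %s", names(meta), vapply(meta, format, character(1))),
             paste0(path, ".meta"))
  invisible(path)
}

#' Read a band image TIFF and its sidecar metadata
#'
#' @param path TIFF path; metadata is read from `<path>.meta` when present.
#' @param nm_per_px Scale override, required if no sidecar provides one.
#' @return A `"band_image"`.
#' @export
read_band_image <- function(path, nm_per_px = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  intensity <- tiff::readTIFF(path)
  if (length(dim(intensity)) == 3) intensity <- intensity[, , 1]
  meta <- list()
  sidecar <- paste0(path, ".meta")
  if (file.exists(sidecar)) meta <- read_run_config(sidecar)
  scale <- nm_per_px %||% meta$nm_per_px
  if (is.null(scale)) {
    stop("nm_per_px not given and no sidecar metadata for ", path)
  }
  structure(
    list(intensity = intensity, nm_per_px = as.numeric(scale),
         tilt_deg = if (!is.null(meta$tilt_deg)) as.numeric(meta$tilt_deg)
                    else NA_real_,
         metadata = meta),
    class = "band_image"
  )
}

#' Parse a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; numeric-looking
#' values are converted to numbers, `true`/`false` to logicals.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (tolower(val) %in% c("true", "false")) {
                    tolower(val) == "true"
                  } else val
  }
  out
}

#' Write a species panel to disk in the pipeline's file layout
#'
#' Creates per-cell `cell_XX_LCP.csv` / `cell_XX_RCP.csv` spectrum files plus
#' a `manifest.csv` (cell_id, channel, path) under `dir/spectra`, per-cell
#' band TIFFs with sidecars under `dir/images`, the panel arc image as
#' `dir/images/arc.tif`, and a `truth.meta` ground-truth record.
#'
#' @param panel A `"species_panel"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_species_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "species_panel"))
  sdir <- file.path(dir, "spectra")
  idir <- file.path(dir, "images")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(idir, recursive = TRUE, showWarnings = FALSE)

  manifest <- do.call(rbind, lapply(panel$cells, function(cell) {
    id <- cell$pair$cell_id
    lcp <- file.path(sdir, paste0(id, "_LCP.csv"))
    rcp <- file.path(sdir, paste0(id, "_RCP.csv"))
    write_spectrum(cell$pair$lcp, lcp)
    write_spectrum(cell$pair$rcp, rcp)
    write_band_image(cell$band_image, file.path(idir, paste0(id, ".tif")))
    data.frame(cell_id = id, channel = c("LCP", "RCP"), path = c(lcp, rcp))
  }))
  utils::write.csv(manifest, file.path(sdir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_band_image(panel$arc_image, file.path(idir, "arc.tif"))
  writeLines(
    sprintf("%s = %s",
            c("pitch_nm", "handedness", "n_turns", "n_mean", "pitch_cv",
              "seed"),
            c(panel$params$pitch_nm, panel$params$handedness,
              panel$params$n_turns, panel$params$n_mean, panel$pitch_cv,
              panel$seed)),
    file.path(dir, "truth.meta")
  )
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
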