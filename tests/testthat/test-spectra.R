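test_that("spectrum files parse across delimiters, headers and row order", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a_LCP.csv")
  writeLines(c("wavelength_nm,reflectance", "450,0.1", "460,0.2"), f1)
  s1 <- read_spectrum(f1)
  expect_s3_class(s1, "spectrum")
  expect_length(s1$wavelength_nm, 2)
  expect_identical(s1$channel, "LCP")
  expect_identical(s1$cell_id, "a")

  f2 <- file.path(d, "b.txt")
  writeLines(c("500\t0.3", "480 0.1", "490\t0.2"), f2) # mixed tab/space, unsorted
  s2 <- read_spectrum(f2, channel = "RCP", cell_id = "b")
  expect_equal(s2$wavelength_nm, c(480, 490, 500))
  expect_equal(s2$reflectance, c(0.1, 0.2, 0.3))

  f3 <- file.path(d, "dup.csv")
  writeLines(c("500,0.1", "500,0.2", "510,0.3"), f3)
  expect_error(read_spectrum(f3, "LCP"), "500")

  f4 <- file.path(d, "empty.csv")
  writeLines(character(), f4)
  expect_error(read_spectrum(f4, "LCP"), "empty")

  f5 <- file.path(d, "bad.csv")
  writeLines(c("450,0.1", "460,abc"), f5)
  expect_error(read_spectrum(f5, "LCP"), "non-numeric")
})

test_that("spectra round-trip through write_spectrum", {
  d <- withr::local_tempdir()
  s <- make_spectrum(c(450, 460, 470), c(0.1, 0.5, 0.2))
  path <- file.path(d, "cell_01_LCP.csv")
  write_spectrum(s, path)
  back <- read_spectrum(path)
  expect_equal(back$wavelength_nm, s$wavelength_nm)
  expect_equal(back$reflectance, s$reflectance)
})

test_that("white/dark normalization reproduces its defining identities", {
  w <- seq(400, 500, 10)
  white <- make_spectrum(w, rep(0.8, 11))
  dark <- make_spectrum(w, rep(0, 11))
  raw_white <- normalize_to_reference(white, white, dark)
  expect_true(all(raw_white$reflectance == 1))
  raw_dark <- normalize_to_reference(dark, white, dark)
  expect_true(all(raw_dark$reflectance == 0))
  mid <- make_spectrum(w, rep(0.4, 11))
  expect_true(all(normalize_to_reference(mid, white, dark)$reflectance == 0.5))
  bad_white <- make_spectrum(w, rep(0, 11))
  expect_error(normalize_to_reference(mid, bad_white, dark), "white <= dark")
})

test_that("resampling interpolates linearly onto the overlap grid", {
  pair <- make_pair(c(400, 410, 420), c(0, 1, 0),
                    c(405, 415, 425), c(1, 0, 1))
  out <- resample_to_common_grid(pair, step_nm = 5)
  expect_equal(out$lcp$wavelength_nm, c(405, 410, 415, 420))
  # hand-computed linear interpolation
  expect_equal(out$lcp$reflectance, c(0.5, 1, 0.5, 0))
  expect_equal(out$rcp$reflectance, c(1, 0.5, 0, 0.5))
  expect_true(out$common_grid)

  same <- make_pair(c(400, 410, 420), c(0, 1, 0), r_r = c(0.2, 0.4, 0.6))
  kept <- resample_to_common_grid(same, step_nm = 10)
  expect_equal(kept$lcp$reflectance, same$lcp$reflectance)
  expect_equal(kept$rcp$reflectance, same$rcp$reflectance)

  disjoint <- make_pair(c(400, 410), c(0, 1), c(700, 710), r_r = c(0, 1))
  expect_error(resample_to_common_grid(disjoint, 5), "disjoint")
})

test_that("peak finding ties break low, flat spectra are undefined, offsets are ignored", {
  w <- seq(400, 800, 10)
  r <- rep(0, length(w))
  r[w == 460] <- 1
  r[w == 520] <- 1
  two <- make_spectrum(w, r)
  expect_equal(find_peak(two, smooth_window = 1)$peak_wavelength_nm, 460)

  flat <- make_spectrum(w, rep(0.3, length(w)))
  pk <- find_peak(flat)
  expect_false(pk$is_defined)
  expect_equal(pk$prominence, 0)

  hp <- helicoid_params(320, "left", 40)
  s <- simulate_cp_spectrum(hp, baseline = 0.05, noise_sd = 0, seed = 1)$lcp
  shifted <- s
  shifted$reflectance <- s$reflectance + 0.2
  a <- find_peak(s); b <- find_peak(shifted)
  expect_equal(a$peak_wavelength_nm, b$peak_wavelength_nm)
  expect_equal(a$prominence, b$prominence, tolerance = 1e-12)

  narrow <- make_spectrum(c(410, 420, 430, 440), rep(1, 4))
  expect_error(find_peak(narrow), "fewer than 5")
})

test_that("noise-free synthetic band peaks within one grid step of n_mean * pitch", {
  for (pitch in c(280, 320, 360)) {
    hp <- panel_params(pitch)
    s <- simulate_cp_spectrum(hp, noise_sd = 0, seed = 1)$lcp
    expect_lte(abs(find_peak(s)$peak_wavelength_nm - 1.5 * pitch), 1)
  }
})

test_that("CP selectivity arithmetic and thresholds behave as specified", {
  w <- seq(400, 800, 5)
  # dominant LCP band peaking at 0.8 over a 0.1 RCP floor
  l <- 0.1 + 0.7 * exp(-((w - 600)^2) / (2 * 20^2))
  r <- rep(0.1, length(w))
  pair <- make_pair(w, l, r_r = r)
  cp <- cp_selectivity(pair, 600, window_nm = 5)
  expect_equal(cp$selectivity_ratio, 8, tolerance = 0.01)
  expect_equal(cp$docp, 0.7 / 0.9, tolerance = 0.01)
  expect_identical(cp$dominant_channel, "LCP")
  expect_true(cp$is_selective)

  eq <- make_pair(w, l, r_r = l)
  cp_eq <- cp_selectivity(eq, 600, window_nm = 5)
  expect_equal(cp_eq$docp, 0)
  expect_false(cp_eq$is_selective)
  expect_error(cp_selectivity(pair, 900), "outside")
})

test_that("selectivity metrics are invariant under common positive rescaling", {
  w <- seq(400, 800, 5)
  l <- 0.1 + 0.7 * exp(-((w - 550)^2) / (2 * 25^2))
  r <- rep(0.08, length(w))
  pair <- make_pair(w, l, r_r = r)
  scaled <- make_pair(w, 0.37 * l, r_r = 0.37 * r)
  a <- cp_selectivity(pair, 550)
  b <- cp_selectivity(scaled, 550)
  expect_equal(a$selectivity_ratio, b$selectivity_ratio, tolerance = 1e-9)
  expect_equal(a$docp, b$docp, tolerance = 1e-9)
})

test_that("every simulated left-handed cell reads as LCP-selective through the pipeline", {
  panel <- simulate_species_panel(panel_params(320), n_cells = 10,
                                  pitch_cv = 0.05, seed = 2,
                                  image_shape = c(32, 64))
  rows <- do.call(rbind, lapply(panel$cells, function(cell) {
    analyze_pair(cell$pair)
  }))
  expect_true(all(rows$is_selective))
  expect_true(all(rows$dominant_channel == "LCP"))
})

test_that("colour bins follow the half-open conventions and partition 400-800 nm", {
  expect_identical(classify_colour_bin(478), "blue")
  expect_identical(classify_colour_bin(536), "green")
  expect_identical(classify_colour_bin(450), "blue")   # boundary to upper bin
  expect_identical(classify_colour_bin(449.99), "violet")
  expect_identical(classify_colour_bin(500), "green")
  expect_identical(classify_colour_bin(570), "long")
  expect_identical(classify_colour_bin(800), "long")
  expect_error(classify_colour_bin(399), "range")
  expect_error(classify_colour_bin(801), "range")
  lambdas <- withr::with_seed(1, stats::runif(500, 400, 800))
  bins <- classify_colour_bin(lambdas)
  expect_true(all(bins %in% c("violet", "blue", "green", "long")))
  # bins are contiguous intervals: sorted wavelengths give sorted bin codes
  code <- match(classify_colour_bin(sort(lambdas)),
                c("violet", "blue", "green", "long"))
  expect_true(all(diff(code) >= 0))
})

test_that("panel summary uses the sample SD and flags single-cell panels", {
  df <- data.frame(peak_wavelength_nm = c(470, 480, 490), is_defined = TRUE,
                   is_selective = TRUE, dominant_channel = "LCP")
  s <- summarize_cells(df)
  expect_equal(s$mean_peak_nm, 480)
  expect_equal(s$sd_peak_nm, 10)
  expect_equal(s$n_cells, 3)
  one <- summarize_cells(df[1, ])
  expect_equal(one$sd_peak_nm, 0)
  expect_true("n1_sd_zero" %in% one$flags)
  none <- data.frame(peak_wavelength_nm = NA_real_, is_defined = FALSE)
  expect_error(summarize_cells(none), "no cell")
})
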