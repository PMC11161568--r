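test_that("noise-free chiral band matches its closed-form centre, width and amplitude", {
  hp <- helicoid_params(320, "left", n_turns = 70,
                        n_ordinary = 1.475, n_extraordinary = 1.525)
  pair <- simulate_cp_spectrum(hp, baseline = 0, noise_sd = 0, seed = 1)
  # oracle: evaluate the stated closed forms directly
  amp <- tanh(70 * pi * 0.05 / (2 * 1.5))^2
  grid <- pair$lcp$wavelength_nm
  expect_equal(grid[which.max(pair$lcp$reflectance)], 480)
  expect_equal(max(pair$lcp$reflectance), amp, tolerance = 1e-10)
  # FWHM = delta_n * pitch = 16 nm: half height at 480 +/- 8
  expect_equal(pair$lcp$reflectance[grid == 488], amp / 2, tolerance = 1e-6)
  expect_equal(pair$lcp$reflectance[grid == 472], amp / 2, tolerance = 1e-6)
  # opposite channel carries no band
  expect_true(all(pair$rcp$reflectance == 0))
})

test_that("band amplitude saturates towards one with many turns", {
  hp <- helicoid_params(320, "left", n_turns = 1e6)
  pair <- simulate_cp_spectrum(hp, baseline = 0, noise_sd = 0, seed = 1)
  expect_equal(max(pair$lcp$reflectance), 1, tolerance = 1e-12)
  # and a right-handed wall puts the band in the RCP channel instead
  hp_r <- helicoid_params(320, "right", n_turns = 70)
  pair_r <- simulate_cp_spectrum(hp_r, baseline = 0, noise_sd = 0, seed = 1)
  expect_gt(max(pair_r$rcp$reflectance), 0.9)
  expect_true(all(pair_r$lcp$reflectance == 0))
})

test_that("zero birefringence gives a zero-width band: matched channel is baseline", {
  hp <- helicoid_params(300, "left", n_turns = 70,
                        n_ordinary = 1.5, n_extraordinary = 1.5)
  pair <- simulate_cp_spectrum(hp, baseline = 0.1, noise_sd = 0, seed = 1)
  expect_true(all(pair$lcp$reflectance == 0.1))
  expect_true(all(pair$rcp$reflectance == 0.1))
})

test_that("spectrum simulation is deterministic in the seed and clipped to [0, 1]", {
  hp <- helicoid_params(320, "left", n_turns = 70)
  a <- simulate_cp_spectrum(hp, noise_sd = 0.05, seed = 7)
  b <- simulate_cp_spectrum(hp, noise_sd = 0.05, seed = 7)
  c <- simulate_cp_spectrum(hp, noise_sd = 0.05, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$lcp$reflectance, c$lcp$reflectance))
  expect_true(all(a$lcp$reflectance >= 0 & a$lcp$reflectance <= 1))
  expect_true(all(a$rcp$reflectance >= 0 & a$rcp$reflectance <= 1))
})

test_that("spectrum simulation rejects bad grids and warns when the band is off-grid", {
  hp <- helicoid_params(320, "left")
  expect_error(simulate_cp_spectrum(hp, grid = c(500, 480, 520)), "ascending")
  expect_error(simulate_cp_spectrum(hp, grid = seq(300, 800, 10)), "within")
  expect_error(simulate_cp_spectrum(hp, noise_sd = -0.1), "noise_sd")
  expect_warning(
    pr <- simulate_cp_spectrum(hp, grid = seq(600, 900, 1), noise_sd = 0,
                               seed = 1),
    "outside"
  )
  expect_true("peak_outside_grid" %in% pr$flags)
})

test_that("helicoid parameter validation enforces the physical invariants", {
  expect_error(helicoid_params(-10, "left"), "pitch")
  expect_error(helicoid_params(320, "left", n_turns = 0), "n_turns")
  expect_error(helicoid_params(320, "left", n_ordinary = 0.9), "n_ordinary")
  expect_error(helicoid_params(320, "left", n_ordinary = 1.5,
                               n_extraordinary = 1.4), "n_extraordinary")
  hp <- helicoid_params(320, "left")
  expect_equal(hp$n_mean, 1.5)
  expect_equal(hp$delta_n, 0.05)
})

test_that("band image has the analytic sinusoidal profile and tilt stretches it", {
  hp <- helicoid_params(320, "left")
  img <- simulate_band_image(hp, nm_per_px = 2, tilt_deg = 0, noise_sd = 0,
                             seed = 1)
  expect_equal(img$metadata$apparent_period_nm / img$nm_per_px, 80)
  expect_equal(img$metadata$true_half_pitch_nm, 160)
  # noise-free column means reproduce the analytic sinusoid exactly
  hp300 <- helicoid_params(300, "left")
  img300 <- simulate_band_image(hp300, nm_per_px = 2, shape = c(128, 512),
                                noise_sd = 0, seed = 1)
  x_nm <- (seq_len(512) - 1) * 2
  expect_equal(colMeans(img300$intensity),
               0.5 + 0.25 * sin(2 * pi * x_nm / 150), tolerance = 1e-12)
  # 60 degree tilt doubles the apparent period
  img60 <- simulate_band_image(hp, nm_per_px = 2, tilt_deg = 60,
                               noise_sd = 0, seed = 1)
  expect_equal(img60$metadata$apparent_period_nm / 2, 160, tolerance = 1e-9)
  expect_error(simulate_band_image(hp, tilt_deg = 85), "tilt")
  expect_error(simulate_band_image(hp, nm_per_px = 0), "nm_per_px")
})

test_that("arc images mirror under handedness flip and record the projected repeat", {
  left <- simulate_arc_image(helicoid_params(320, "left", 70),
                             cut_angle_deg = 30, seed = 11)
  right <- simulate_arc_image(helicoid_params(320, "right", 70),
                              cut_angle_deg = 30, seed = 11)
  flipped <- right$intensity[, rev(seq_len(ncol(right$intensity)))]
  expect_equal(left$intensity, flipped, tolerance = 1e-12)
  expect_equal(left$metadata$arc_repeat_nm, 160 / sin(30 * pi / 180))
  expect_error(simulate_arc_image(helicoid_params(320, "left"),
                                  cut_angle_deg = 2), "cut_angle")
})

test_that("arc texture outscores a matched uniform-noise image", {
  hp <- helicoid_params(320, "left", 70)
  arc <- simulate_arc_image(hp, cut_angle_deg = 30, seed = 4)
  noise <- simulate_noise_image(shape = dim(arc$intensity), seed = 4)
  expect_gt(arc_score(arc), arc_score(noise))
})

test_that("species panels are deterministic and collapse to one pitch at zero CV", {
  hp <- panel_params(320)
  p0 <- simulate_species_panel(hp, n_cells = 4, pitch_cv = 0, seed = 5,
                               image_shape = c(32, 64))
  pitches <- vapply(p0$cells, function(cell) cell$pitch_nm, numeric(1))
  expect_true(all(pitches == 320))
  a <- simulate_species_panel(hp, n_cells = 3, pitch_cv = 0.05, seed = 9,
                              image_shape = c(32, 64))
  b <- simulate_species_panel(hp, n_cells = 3, pitch_cv = 0.05, seed = 9,
                              image_shape = c(32, 64))
  expect_identical(a, b)
  expect_error(simulate_species_panel(hp, pitch_cv = 0.5), "pitch_cv")
  expect_error(simulate_species_panel(hp, n_cells = 0), "n_cells")
})

test_that("per-cell peak wavelengths average to n_mean * pitch (Monte Carlo)", {
  hp <- panel_params(320)
  panel <- simulate_species_panel(hp, n_cells = 100, pitch_cv = 0.05,
                                  seed = 12, image_shape = c(32, 64))
  peaks <- vapply(panel$cells, function(cell) {
    find_peak(cell$pair$lcp)$peak_wavelength_nm
  }, numeric(1))
  se <- 0.05 * 480 / sqrt(100)
  expect_lt(abs(mean(peaks) - 480), 2 * se)
})

test_that("opposite-channel prominence stays at the noise floor (handedness exclusivity)", {
  hp <- panel_params(320)
  panel <- simulate_species_panel(hp, n_cells = 10, pitch_cv = 0.05,
                                  seed = 3, image_shape = c(32, 64))
  for (cell in panel$cells) {
    pk_opp <- find_peak(cell$pair$rcp)
    pk_match <- find_peak(cell$pair$lcp)
    # opposite channel never clears the relative-prominence selectivity bar
    expect_lt(pk_opp$prominence, 0.05 * pk_match$peak_reflectance)
  }
})
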