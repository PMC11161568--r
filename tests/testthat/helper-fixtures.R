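# in-code fixtures shared across test files

make_spectrum <- function(wavelength, reflectance, channel = "LCP",
                          cell_id = "c1") {
  structure(
    list(wavelength_nm = wavelength, reflectance = reflectance,
         channel = channel, cell_id = cell_id),
    class = "spectrum"
  )
}

make_pair <- function(w_l, r_l, w_r = w_l, r_r, cell_id = "c1",
                      common_grid = identical(w_l, w_r)) {
  structure(
    list(lcp = make_spectrum(w_l, r_l, "LCP", cell_id),
         rcp = make_spectrum(w_r, r_r, "RCP", cell_id),
         cell_id = cell_id, common_grid = common_grid, flags = character()),
    class = "cell_spectrum_pair"
  )
}

# default panel ground truth used in recovery tests: mid-range turn count
panel_params <- function(pitch_nm, handedness = "left") {
  helicoid_params(pitch_nm, handedness, n_turns = 40)
}
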