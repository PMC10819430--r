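# Shared fixture builders. Everything is generated in code; no binary data.

# Gaussian emission band sampled on an integer wavelength grid
gaussian_spectrum <- function(centre_nm, height = 1000, sd_nm = 25,
                              wavelengths = 275:500) {
  data.frame(wavelength_nm = wavelengths,
             intensity = height * exp(-(wavelengths - centre_nm)^2 / (2 * sd_nm^2)))
}

# minimal single-wavelength titration table with prescribed intensities;
# handy when a test needs exact F values rather than full spectra
flat_titration <- function(conc, f, temperature_K = 298, series_id = "flat") {
  as_titration(tibble::tibble(
    series_id = series_id, temperature_K = temperature_K,
    ligand_conc_M = conc, wavelength_nm = 340, intensity = f))
}

# simulator configuration without the emission blue shift: the forward
# model is then the exact algebraic inverse of the fits at a fixed
# reference wavelength
noshift_config <- function(...) {
  sim_config(peak_bound_nm = 337, peak_free_nm = 337, ...)
}

# dense two-hump EEM grid (protein peaks A and B)
two_peak_eem <- function(height_a = 1000, height_b = 600) {
  ex <- seq(220, 400, by = 5)
  em <- seq(280, 550, by = 2)
  g <- expand.grid(excitation_nm = ex, emission_nm = em)
  g$intensity <-
    height_a * exp(-((g$excitation_nm - 280)^2 / (2 * 12^2) +
                     (g$emission_nm - 337)^2 / (2 * 15^2))) +
    height_b * exp(-((g$excitation_nm - 230)^2 / (2 * 12^2) +
                     (g$emission_nm - 340)^2 / (2 * 15^2)))
  as_eem(g)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
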