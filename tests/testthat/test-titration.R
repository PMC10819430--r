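test_that("titration CSV reading validates structure and round-trips the simulator", {
  cfg <- sim_config(noise_sd_rel = 0.01, seed = 7)
  s <- simulate_titration(cfg, 298)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture(s, path)

  back <- read_titration_csv(path)
  expect_equal(nrow(back), nrow(s))
  expect_equal(back$intensity, s$intensity, tolerance = 1e-12)
  expect_equal(back$ligand_conc_M, s$ligand_conc_M, tolerance = 1e-12)
  expect_identical(dplyr::first(back$ligand_conc_M), 0)

  # ground truth survives the header round trip
  tr <- ground_truth(back)
  expect_equal(tr$kb_true, ground_truth(s)$kb_true)
  expect_equal(tr$n_true, ground_truth(s)$n_true)
  expect_equal(tr$seed, ground_truth(s)$seed)

  # constructed shape: 7 concentrations x 226 wavelengths
  expect_equal(dplyr::n_distinct(s$ligand_conc_M), 7)
  expect_equal(sum(s$ligand_conc_M == 0), 226)
})

test_that("malformed titration tables are rejected with informative errors", {
  cfg <- sim_config(noise_sd_rel = 0)
  s <- simulate_titration(cfg, 298)

  # missing zero-concentration reference
  nozero <- s[s$ligand_conc_M > 0, ]
  expect_error(as_titration(nozero), class = "quenchbind_validation_error")

  # missing column is named
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- as.data.frame(s)[, setdiff(names(s), "intensity")]
  readr::write_csv(bad, path)
  expect_error(read_titration_csv(path), "intensity",
               class = "quenchbind_format_error")

  # non-monotone wavelengths within one spectrum
  shuffled <- as.data.frame(s)
  i <- which(shuffled$ligand_conc_M == 0)[1:2]
  shuffled[i, "wavelength_nm"] <- rev(shuffled[i, "wavelength_nm"])
  expect_error(as_titration(shuffled), class = "quenchbind_validation_error")

  # absorbance columns must come in pairs
  half <- as.data.frame(s)
  half$a_ex <- 0.1
  expect_error(as_titration(half), class = "quenchbind_validation_error")
})

test_that("inner-filter correction follows F_obs * 10^((Aex+Aem)/2) and inverts the simulator", {
  expect_identical(correct_inner_filter(100, 0, 0), 100)
  expect_equal(correct_inner_filter(100, 0.1, 0.1), 100 * 10^0.1, tolerance = 1e-12)
  expect_true(all(correct_inner_filter(c(5, 50), 0.2, 0.05) >= c(5, 50)))
  expect_error(correct_inner_filter(100, -0.1, 0), class = "quenchbind_domain_error")

  a_ex <- seq(0, 0.3, length.out = 7)
  a_em <- seq(0, 0.15, length.out = 7)
  attenuated <- simulate_titration(sim_config(noise_sd_rel = 0, a_ex = a_ex, a_em = a_em), 298)
  clean <- simulate_titration(sim_config(noise_sd_rel = 0), 298)
  restored <- correct_inner_filter(attenuated$intensity, attenuated$a_ex, attenuated$a_em)
  expect_rel_error(restored[clean$intensity > 0], clean$intensity[clean$intensity > 0], 1e-9)
})

test_that("series_intensities honours both extraction policies", {
  s <- simulate_titration(sim_config(noise_sd_rel = 0), 298)
  fixed <- series_intensities(s, policy = "fixed_reference")
  expect_equal(nrow(fixed), 7)
  expect_equal(fixed$ligand_conc_M[1], 0)
  expect_equal(fixed$f[1], 1000)
  # static quenching: F strictly decreasing with concentration
  expect_true(all(diff(fixed$f) < 0))

  # per-spectrum max equals each spectrum's maximum despite the drifting peak
  mx <- series_intensities(s, policy = "per_spectrum_max")
  by_hand <- tapply(s$intensity, s$ligand_conc_M, max)
  expect_equal(mx$f, as.numeric(by_hand[order(as.numeric(names(by_hand)))]))

  # the per-spectrum max tracks the band height F(Q) = f0/(1 + Kb Q^n)
  truth <- ground_truth(s)
  expect_rel_error(mx$f, truth$f0 / (1 + truth$kb_true * mx$ligand_conc_M^truth$n_true),
                   1e-3)

  expect_error(series_intensities(s, reference_nm = 600),
               class = "quenchbind_domain_error")
})

test_that("peak metrics report shift direction, magnitude and quench percentage", {
  ref <- gaussian_spectrum(337, height = 1000)

  same <- peak_metrics(ref, ref)
  expect_equal(same$delta_lambda_nm, 0)
  expect_identical(same$shift_class, "none")
  expect_equal(same$quench_pct, 0)

  # blue-shifted band at 69.4% of the reference height
  shifted <- gaussian_spectrum(317, height = 694)
  pm <- peak_metrics(shifted, ref)
  expect_equal(pm$delta_lambda_nm, -20)
  expect_identical(pm$shift_class, "blue")
  expect_equal(pm$quench_pct, 30.6, tolerance = 1e-12)

  # antisymmetry of the shift under swapping spectrum and reference
  expect_equal(peak_metrics(ref, shifted)$delta_lambda_nm, 20)
  expect_identical(peak_metrics(ref, shifted)$shift_class, "red")

  # tolerance rule partitions the classes
  expect_identical(peak_metrics(gaussian_spectrum(336.6), ref)$shift_class, "none")
  expect_error(peak_metrics(ref, gaussian_spectrum(337, height = 0)),
               class = "quenchbind_domain_error")
})

test_that("parabolic refinement recovers a sub-grid peak centre", {
  sp <- gaussian_spectrum(336.4)
  coarse <- peak_metrics(sp, sp)$lambda_max_nm
  refined <- peak_metrics(sp, sp, refine = TRUE)$lambda_max_nm
  expect_equal(coarse, 336) # grid argmax
  expect_lt(abs(refined - 336.4), 0.1)

  # dense-grid oracle: a 0.01 nm grid pins the true centre
  dense <- gaussian_spectrum(336.4, wavelengths = seq(275, 500, by = 0.01))
  oracle <- dense$wavelength_nm[which.max(dense$intensity)]
  expect_lt(abs(refined - oracle), 0.1)
})

test_that("EEM peak picking finds seeded humps within the search window", {
  grid <- two_peak_eem()
  seeds <- data.frame(label = c("A", "B"),
                      excitation_nm = c(280, 230), emission_nm = c(337, 340))
  pk <- eem_peaks(grid, seeds)
  expect_equal(pk$excitation_nm, c(280, 230))
  # the 2 nm emission grid brackets hump A's 337 nm centre at 336/338;
  # the second hump's tail tips the balance to 338
  expect_equal(pk$emission_nm, c(338, 340))

  # quenched grid at 62.2% of the original: 37.8% intensity reduction
  quenched <- two_peak_eem(height_a = 622, height_b = 600)
  pk2 <- eem_peaks(quenched, seeds)
  expect_equal((1 - pk2$intensity[1] / pk$intensity[1]) * 100, 37.8, tolerance = 0.01)

  # a small radius is confined to the local window, not the global maximum
  far_seed <- data.frame(label = "off", excitation_nm = 350, emission_nm = 500)
  local_pk <- eem_peaks(grid, far_seed, search_radius_nm = 10)
  expect_lt(local_pk$intensity, pk$intensity[2])
  expect_lte(abs(local_pk$excitation_nm - 350), 10)

  expect_error(eem_peaks(grid, data.frame(label = "x", excitation_nm = 100,
                                          emission_nm = 300)),
               class = "quenchbind_domain_error")
})

test_that("synchronous-fluorescence scans are representable as ordinary series", {
  # a delta-lambda = 60 nm scan: the scan axis plays the wavelength role
  wl <- 200:400
  rows <- purrr::map(c(0, 5e-6, 1e-5), function(q) {
    tibble::tibble(series_id = "sync60", temperature_K = 298, ligand_conc_M = q,
                   wavelength_nm = wl,
                   intensity = 800 / (1 + 4e4 * q) * exp(-(wl - 280)^2 / (2 * 12^2)))
  })
  sync <- as_titration(purrr::list_rbind(rows))
  f <- series_intensities(sync)
  expect_equal(nrow(f), 3)
  expect_true(all(diff(f$f) < 0))
})
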