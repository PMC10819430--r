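test_that("the zero-ligand point reproduces f0 at the free peak exactly", {
  s <- simulate_titration(sim_config(noise_sd_rel = 0), 298)
  f0spec <- s[s$ligand_conc_M == 0, ]
  expect_equal(max(f0spec$intensity), 1000)
  expect_equal(f0spec$wavelength_nm[which.max(f0spec$intensity)], 337)
})

test_that("peak height falls and peak position migrates monotonically with dose", {
  s <- simulate_titration(sim_config(kb = 2e5, noise_sd_rel = 0), 298)
  per_spec <- s |>
    dplyr::group_by(ligand_conc_M) |>
    dplyr::summarise(height = max(intensity),
                     centre = wavelength_nm[which.max(intensity)], .groups = "drop") |>
    dplyr::arrange(ligand_conc_M)
  expect_true(all(diff(per_spec$height) < 0))
  # blue shift: centre moves from the free peak toward the bound peak
  expect_true(all(diff(per_spec$centre) <= 0))
  expect_equal(per_spec$centre[1], 337)
  expect_gte(min(per_spec$centre), 317)
})

test_that("a fixed seed gives bit-identical series and the RNG stream is preserved", {
  cfg <- sim_config(noise_sd_rel = 0.02, seed = 99)
  a <- simulate_titration(cfg, 298)
  b <- simulate_titration(cfg, 298)
  expect_identical(a$intensity, b$intensity)
  c_ <- simulate_titration(sim_config(noise_sd_rel = 0.02, seed = 100), 298)
  expect_false(identical(a$intensity, c_$intensity))

  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(simulate_titration(cfg, 298)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("temperature dependence of the simulated Kb follows the Van't Hoff relation", {
  cfg <- sim_config(delta_h_kj_mol = -106.57, delta_s_j_mol_k = -259.2,
                    noise_sd_rel = 0)
  R <- 8.314
  for (t_k in c(298, 304, 310)) {
    expect_rel_error(kb_at_temperature(cfg, t_k),
                     exp(106.57 * 1000 / (R * t_k) - 259.2 / R), 1e-12)
  }
  # fitting the simulated study returns the generating pair exactly
  study <- simulate_study(noshift_config(delta_h_kj_mol = -106.57,
                                         delta_s_j_mol_k = -259.2, noise_sd_rel = 0))
  vh <- vant_hoff_fit(binding_table(study)[, c("temperature_K", "kb")])
  expect_rel_error(vh$delta_h_kj_mol, -106.57, 1e-9)
  expect_rel_error(vh$delta_s_j_mol_k, -259.2, 1e-9)
})

test_that("fixture files round-trip series, metadata and ground truth", {
  cfg <- sim_config(kb = 3.7e6, n_sites = 1.49, noise_sd_rel = 0.01, seed = 5,
                    a_ex = seq(0, 0.12, length.out = 7),
                    a_em = seq(0, 0.06, length.out = 7))
  s <- simulate_titration(cfg, 304)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture(s, path)
  back <- read_titration_csv(path)

  expect_equal(back$intensity, s$intensity, tolerance = 1e-12)
  expect_equal(back$a_ex, s$a_ex, tolerance = 1e-12)
  expect_equal(attr(back, "protein_conc_M"), 1e-6)
  expect_equal(attr(back, "excitation_nm"), 275)
  tr <- ground_truth(back)
  expect_equal(tr$kb_true, 3.7e6)
  expect_equal(tr$n_true, 1.49)
  expect_identical(tr$mode, "binding")

  # inner-filter correction restores the unattenuated forward model
  clean <- simulate_titration(sim_config(kb = 3.7e6, n_sites = 1.49,
                                         noise_sd_rel = 0.01, seed = 5), 304)
  restored <- correct_inner_filter(back$intensity, back$a_ex, back$a_em)
  keep <- clean$intensity != 0
  expect_rel_error(restored[keep], clean$intensity[keep], 1e-9)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(concentrations_M = c(3, 6) * 1e-6),
               class = "quenchbind_validation_error")
  expect_error(sim_config(bandwidth_nm = 0), class = "quenchbind_validation_error")
  expect_error(sim_config(kb = -1), class = "quenchbind_validation_error")
  expect_error(sim_config(delta_h_kj_mol = -100), class = "quenchbind_validation_error")
  expect_error(sim_config(mode = "stern_volmer"), class = "quenchbind_validation_error")
  expect_error(sim_config(a_ex = c(0.1, 0.2), a_em = c(0.1, 0.2)),
               class = "quenchbind_validation_error")
})

test_that("end-to-end pipeline recovers kb and dH from noisy multi-temperature studies", {
  # 100 seeded replicates at 1% noise, inner-filter attenuation included
  truth_dh <- -106.57; truth_ds <- -259.2
  res <- purrr::map(1:100, function(i) {
    cfg <- sim_config(delta_h_kj_mol = truth_dh, delta_s_j_mol_k = truth_ds,
                      noise_sd_rel = 0.01, seed = i,
                      a_ex = seq(0, 0.1, length.out = 7),
                      a_em = seq(0, 0.05, length.out = 7))
    study <- simulate_study(cfg)
    bt <- binding_table(study, policy = "per_spectrum_max")
    vh <- glance(vant_hoff_fit(bt[, c("temperature_K", "kb")]))
    tibble::tibble(kb_298 = bt$kb[bt$temperature_K == 298],
                   dh = vh$delta_h_kj_mol)
  }) |> purrr::list_rbind()
  kb_true_298 <- kb_at_temperature(
    sim_config(delta_h_kj_mol = truth_dh, delta_s_j_mol_k = truth_ds), 298)
  expect_lt(abs(median(res$kb_298) - kb_true_298) / kb_true_298, 0.10)
  expect_lt(abs(median(res$dh) - truth_dh), 5)
})
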