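test_that("Stern-Volmer fit inverts the linear quenching law", {
  q <- c(0, 3, 6, 9, 12, 15, 18) * 1e-6
  f0 <- 1200
  exact <- flat_titration(q, f0 / (1 + 2.5e4 * q))
  fit <- stern_volmer_fit(exact)
  expect_rel_error(fit$ksv, 2.5e4, 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 7)

  # through the full spectral simulator as well
  s <- simulate_titration(noshift_config(mode = "stern_volmer", ksv = 2.5e4,
                                         noise_sd_rel = 0), 298)
  expect_rel_error(stern_volmer_fit(s)$ksv, 2.5e4, 1e-10)
})

test_that("the bimolecular quenching constant is Ksv / tau0 exactly", {
  q <- c(0, 3, 6, 9, 12, 15, 18) * 1e-6
  fit <- stern_volmer_fit(flat_titration(q, 1000 / (1 + 2.52e4 * q)))
  expect_identical(fit$kq, fit$ksv / 1e-8)
  expect_equal(fit$kq, 2.52e12, tolerance = 1e-9)

  fit2 <- stern_volmer_fit(flat_titration(q, 1000 / (1 + 2.52e4 * q)), tau0_s = 5e-9)
  expect_identical(fit2$kq, fit2$ksv / 5e-9)
})

test_that("degenerate and invalid quenching inputs are handled", {
  q <- c(0, 3, 6, 9) * 1e-6
  # no quenching: zero slope, unit intercept
  fit <- stern_volmer_fit(flat_titration(q, rep(500, 4)))
  expect_equal(fit$ksv, 0, tolerance = 1e-12)
  expect_equal(fit$intercept, 1)

  expect_error(stern_volmer_fit(flat_titration(q, c(500, 400, -1, 300))),
               class = "quenchbind_domain_error")
  expect_error(stern_volmer_fit(flat_titration(c(0, 3e-6), c(500, 400))),
               class = "quenchbind_validation_error")
})

test_that("mechanism classification follows the Ksv trend / Kq decision table", {
  mk <- function(ksv) tibble::tibble(temperature_K = c(298, 304, 310),
                                     ksv = ksv, kq = ksv / 1e-8)
  # falling Ksv: ground-state complexation weakens with temperature
  expect_identical(classify_mechanism(mk(c(2.52e4, 2.35e4, 1.27e4)))$mechanism, "static")
  # rising Ksv but Kq far above the diffusion limit
  expect_identical(classify_mechanism(mk(c(1.39e4, 1.46e4, 1.47e4)))$mechanism, "mixed")
  # rising Ksv with Kq below the diffusion limit: purely collisional
  dyn <- tibble::tibble(temperature_K = c(298, 304, 310), ksv = c(50, 100, 150),
                        kq = c(0.5e10, 1.0e10, 1.5e10))
  expect_identical(classify_mechanism(dyn)$mechanism, "dynamic")
  expect_false(classify_mechanism(dyn)$kq_exceeds_diffusion_limit)
  # flat and non-monotonic trends
  expect_identical(classify_mechanism(mk(c(1e4, 1e4, 1e4)))$trend, "flat")
  expect_identical(classify_mechanism(mk(c(1e4, 1e4, 1e4)))$mechanism, "static")
  nonmono <- classify_mechanism(mk(c(1e4, 2e4, 1.5e4)))
  expect_identical(nonmono$trend, "non_monotonic")
  flat_low <- classify_mechanism(tibble::tibble(
    temperature_K = c(298, 310), ksv = c(100, 100), kq = c(1e9, 1e9)))
  expect_identical(flat_low$mechanism, "indeterminate")

  expect_error(classify_mechanism(mk(c(1, 1, 1))[1, ]),
               class = "quenchbind_validation_error")
})

test_that("classification is invariant under rescaling that preserves the Kq comparison", {
  base <- tibble::tibble(temperature_K = c(298, 304, 310),
                         ksv = c(2.52e4, 2.35e4, 1.27e4))
  base$kq <- base$ksv / 1e-8
  for (c_scale in c(0.5, 2, 10)) {
    scaled <- dplyr::mutate(base, ksv = ksv * c_scale, kq = kq * c_scale)
    same_side <- (max(scaled$kq) > 2e10) == (max(base$kq) > 2e10)
    if (same_side) {
      expect_identical(classify_mechanism(scaled)$mechanism,
                       classify_mechanism(base)$mechanism)
    }
  }
  # scaling across the diffusion limit can change the call
  tiny <- dplyr::mutate(base, ksv = ksv * 1e-8, kq = kq * 1e-8)
  expect_identical(classify_mechanism(tiny)$mechanism, "static") # decreasing stays static
})

test_that("sv_table fits every temperature of a study and feeds the classifier", {
  cfg <- noshift_config(mode = "stern_volmer", ksv = 2.0e4, noise_sd_rel = 0)
  study <- simulate_study(cfg)
  tab <- sv_table(study)
  expect_equal(nrow(tab), 3)
  expect_rel_error(tab$ksv, rep(2e4, 3), 1e-9)
  call <- classify_mechanism(tab)
  expect_identical(call$trend, "flat")
})
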