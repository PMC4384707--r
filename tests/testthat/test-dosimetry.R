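test_that("per-decay alpha energy is the yield-weighted line sum", {
  expect_equal(mean_alpha_energy(alpha_spectrum(1, 5.87, 7.214)), 5.87)
  expect_equal(mean_alpha_energy(alpha_spectrum(c(0.5, 0.5), c(2, 4), 7.214)), 3)
  # two-line astatine case, frozen from the explicit two-term product sum:
  # 0.418*5.87 + 0.582*7.45 = 2.45366 + 4.33590
  two <- alpha_spectrum(c(0.418, 0.582), c(5.87, 7.45), 7.214)
  expect_equal(mean_alpha_energy(two), 6.78956)
  flipped <- alpha_spectrum(c(0.582, 0.418), c(7.45, 5.87), 7.214)
  expect_equal(mean_alpha_energy(flipped), mean_alpha_energy(two))
})

test_that("spectrum validation rejects unusable nuclide definitions", {
  expect_error(alpha_spectrum(numeric(), numeric(), 7), "unusable")
  expect_error(alpha_spectrum(1.2, 5, 7), "yields")
  expect_error(alpha_spectrum(0.5, -1, 7), "energies")
  expect_error(alpha_spectrum(0.5, 5, 0), "half_life")
  expect_equal(spectrum_half_life(at211_spectrum()), 7.214)
})

test_that("extension holds the biodistribution and decays it physically", {
  hl <- 7.214
  # physical curve: one extra half-life halves the last activity
  crv <- tac("x", c(0, 24), c(100, 40))
  ext <- extend_tac(crv, 24 + hl, half_life_h = hl, step_h = hl)
  expect_equal(tail(ext$activity_bq, 1), 20)
  # decay-corrected curve reaches the same physical activity at the horizon
  dc <- tac("x", c(0, 24), c(100, 40 / exp(-log(2) / hl * 24)),
            decay_corrected = TRUE)
  ext_dc <- extend_tac(dc, 24 + hl, half_life_h = hl, step_h = hl)
  lam <- log(2) / hl
  phys_end <- tail(ext_dc$activity_bq, 1) * exp(-lam * (24 + hl))
  expect_equal(phys_end, 20, tolerance = 1e-12)
  # horizon at or before the last sample is a no-op
  expect_equal(extend_tac(crv, 24, half_life_h = hl), crv)
  expect_equal(extend_tac(crv, 10, half_life_h = hl), crv)
})

test_that("extension grid fineness barely matters when half-life >> step", {
  hl <- 7.214
  lam <- log(2) / hl
  crv <- tac("x", c(0, 24), c(100, 50))
  # 2 h extension sampled with 10 vs 1000 grid points: both within 1% of the
  # closed-form exponential tail, and within 1e-4 of each other
  closed <- 50 * (1 - exp(-lam * 2)) / lam * 3600
  got <- vapply(c(2 / 10, 2 / 1000), function(step) {
    ext <- extend_tac(crv, 26, half_life_h = hl, step_h = step)
    cumulated_activity(ext, 24, 26)$decays
  }, numeric(1))
  expect_true(all(abs(got - closed) / closed < 0.01))
  expect_lt(abs(got[1] - got[2]) / closed, 1e-3)
})

test_that("cumulated activity integrates the trapezoid in decays", {
  expect_equal(cumulated_activity(tac("x", c(0, 1), c(1, 1)), 0, 1)$decays, 3600)
  expect_equal(cumulated_activity(tac("x", c(0, 1), c(0, 2)), 0, 1)$decays, 3600)
  # off-grid endpoints are linearly interpolated: constant 2 Bq over 30 min
  expect_equal(cumulated_activity(tac("x", c(0, 1), c(2, 2)), 0.25, 0.75)$decays,
               2 * 0.5 * 3600)
  expect_error(cumulated_activity(tac("x", c(0, 1), c(1, 1)), 0, 2), "outside")
  expect_error(cumulated_activity(tac("x", c(0, 1), c(1, 1)), 1, 1), "exceed")
})

test_that("trapezoid matches a fine Riemann oracle on uneven curves", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      t <- sort(c(0, runif(3, 0.2, 9.5), 10))
      a <- runif(5, 0, 50)
      crv <- tac("x", t, a)
      got <- cumulated_activity(crv, 0, 10)$decays
      # brute-force Riemann midpoint sum on the linear interpolant, 1e5 steps
      grid <- seq(0, 10, length.out = 1e5 + 1)
      mid <- (head(grid, -1) + tail(grid, -1)) / 2
      oracle <- sum(approx(t, a, xout = mid)$y * diff(grid)) * 3600
      expect_lt(abs(got - oracle) / oracle, 1e-3)
    }
  })
})

test_that("organ dose follows the MIRD product with unit conversion", {
  spec1 <- alpha_spectrum(1, 1, 7.2)
  expect_equal(organ_dose(1e9, spec1, 1e-3), 160.2176634)
  expect_equal(organ_dose(0, spec1, 1e-3), 0)
  expect_equal(organ_dose(1e9, spec1, 2e-3), organ_dose(1e9, spec1, 1e-3) / 2)
  expect_equal(organ_dose(1e9, spec1, 1e-3, absorbed_fraction = 0.5),
               organ_dose(1e9, spec1, 1e-3) / 2)
  expect_error(organ_dose(1e9, spec1, 0), "mass")
  expect_error(organ_dose(-1, spec1, 1e-3), ">= 0")
})

test_that("dose scales linearly with injected activity", {
  expect_equal(signif_report(scale_dose(0.29, 1.7, 105)), 18)
  expect_equal(signif_report(scale_dose(5.7, 1.7, 7.5)), 25)
  expect_equal(scale_dose(3.3, 2, 2), 3.3)
  expect_error(scale_dose(1, 0, 5), "> 0")
})

test_that("dose table reproduces closed forms, exact activity ratios, and reruns bit-identically", {
  spec <- at211_spectrum()
  orgs <- tibble::tibble(organ = c("a", "b"), mass_kg = c(1e-4, 2e-4))
  # constant physical activity: rectangle dose
  crv <- tac(rep(c("a", "b"), each = 2), c(0, 6, 0, 6), c(5, 5, 8, 8))
  win <- tibble::tibble(activity_kbq = c(1.7, 105), t_end_h = c(1, 1))
  dt <- dose_table(crv, orgs, spec, win, reference_activity_kbq = 1.7)
  d_a <- organ_dose(5 * 3600, spec, 1e-4)
  expect_equal(dt$dose_mgy[dt$organ == "a" & dt$activity_kbq == 1.7], d_a)
  ratio <- dt$dose_mgy[dt$activity_kbq == 105] / dt$dose_mgy[dt$activity_kbq == 1.7]
  expect_equal(ratio, rep(105 / 1.7, 2))
  # determinism on randomized curves
  withr::with_seed(77, {
    rcrv <- tac(rep("a", 6), c(0, sort(runif(5, 0.5, 24))), runif(6, 0, 30))
  })
  w2 <- tibble::tibble(activity_kbq = c(1.7, 7.5), t_end_h = c(6, 48))
  t1 <- dose_table(rcrv, orgs[1, ], spec, w2)
  t2 <- dose_table(rcrv, orgs[1, ], spec, w2)
  expect_identical(t1, t2)
  expect_error(dose_table(crv, tibble::tibble(organ = "a", mass_kg = 1e-4), spec, win),
               "geometry.*b")
  expect_error(dose_table(crv[crv$organ == "a", ], orgs, spec, win), "curve.*b")
})

test_that("dose is monotone in the window end and linear in curve activity", {
  spec <- at211_spectrum()
  withr::with_seed(42, {
    crv <- tac("x", sort(c(0, runif(8, 0.1, 23), 24)), runif(10, 0, 40))
  })
  ends <- c(1, 3, 6, 12, 24)
  d <- vapply(ends, function(e) {
    organ_dose(cumulated_activity(crv, 0, e)$decays, spec, 1e-4)
  }, numeric(1))
  expect_true(all(diff(d) >= 0))
  crv2 <- dplyr::mutate(crv, activity_bq = 2 * activity_bq)
  d2 <- organ_dose(cumulated_activity(crv2, 0, 24)$decays, spec, 1e-4)
  expect_equal(d2, 2 * organ_dose(cumulated_activity(crv, 0, 24)$decays, spec, 1e-4))
})

test_that("mean dose rate of a pure-decay curve decreases with time", {
  hl <- 7.214
  lam <- log(2) / hl
  t <- seq(0, 72, by = 0.1)
  crv <- tac("x", t, 100 * exp(-lam * t))
  ends <- c(1, 2, 6, 12, 24, 48, 72)
  rate <- vapply(ends, function(e) {
    cumulated_activity(crv, 0, e)$decays / e
  }, numeric(1))
  expect_true(all(diff(rate) < 0))
})
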