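test_that("delay schedule follows the linearly increasing step rule", {
  s <- build_delay_schedule(a = 7, n_gates = 3, initial_delay = 0)
  expect_equal(s$delays, c(0, 7, 21))          # increments 7, 14
  # linearity in a: a = 15 scales all offsets by 15/7
  s7 <- build_delay_schedule(7, 21, 0)
  s15 <- build_delay_schedule(15, 21, 0)
  expect_equal(s15$delays, s7$delays * 15 / 7)
  expect_equal(build_delay_schedule(7, 1, 12)$delays, 12)
  # default ambient schedule: 21 gates, 12 us initial, last at 1482 us
  d <- build_delay_schedule()
  expect_equal(d$delays[1], 12)
  expect_equal(d$delays[21], 12 + 7 * 20 * 21 / 2)
  expect_true(all(diff(d$delays) > 0))
  expect_error(build_delay_schedule(a = 0), "positive")
})

test_that("lifetime_from_decay is exact, scale invariant, and guarded", {
  d <- build_delay_schedule()
  tr <- exp(-d$delays / 1000 / 0.109)
  f <- lifetime_from_decay(d$delays, tr)
  expect_equal(f$tau, 0.109, tolerance = 1e-4)
  f2 <- lifetime_from_decay(d$delays, 3.7e4 * tr)
  expect_equal(f2$tau, f$tau, tolerance = 1e-10)
  expect_error(lifetime_from_decay(d$delays, rep(5, 21)), "decay")
  expect_error(lifetime_from_decay(d$delays[1:4], tr[1:4]), "5 positive")
})

test_that("Horrocks hydration numbers reproduce the worked values", {
  h <- horrocks_hydration(0.385)
  expect_equal(h$n_H2O, 1.05 / 0.385 - 0.44, tolerance = 1e-12)
  expect_equal(h$n_H2O, 2.29, tolerance = 0.005)
  expect_equal(h$nearest_integer, 2)
  expect_equal(h$band, 0.5)
  # cryogenic lifetime ~1 ms: 0.61, inside the "0 or 1" band
  h1 <- horrocks_hydration(1.0)
  expect_equal(h1$n_H2O, 0.61, tolerance = 1e-12)
  expect_true(h1$n_H2O - h1$band <= 1 && h1$n_H2O + h1$band >= 0)
  expect_equal(horrocks_hydration(0.109)$n_H2O, 9.19, tolerance = 0.005)
  # strictly decreasing in tau
  taus <- seq(0.05, 2, length.out = 50)
  expect_true(all(diff(horrocks_hydration(taus)$n_H2O) < 0))
  expect_error(horrocks_hydration(0), "positive")
})

test_that("noiseless rank-1 cube is recovered exactly", {
  cube <- gen_trlfs_cube(species = list(), lifetimes = 0.109,
                         brightness = 1,
                         wavelength = seq(570, 720, by = 3),
                         ligand_total = seq(0, 112e-6, length.out = 8),
                         seed = 3)
  truth <- attr(cube, "truth")
  f <- parafac_fit(cube, 1, "free", seed = 1)
  expect_true(f$converged)
  expect_gte(.cos <- sum(f$B[, 1] * truth$spectra[, 1]) /
               sqrt(sum(f$B[, 1]^2) * sum(truth$spectra[, 1]^2)), 0.999999)
  expect_lt(abs(f$lifetimes - 0.109) / 0.109, 1e-3)
  expect_equal(f$concentration_profiles[, 1],
               truth$concentration_profiles[, 1], tolerance = 1e-3)
  # reconstruction explains >= 99% of variance
  expect_lt(f$residual_fraction, 0.01)
})

test_that("two-species recovery at SNR 50 meets the identifiability bar", {
  cube <- small_cube(snr = 50, seed = 11)
  truth <- attr(cube, "truth")
  f <- parafac_fit(cube, 2, "free", seed = 1)
  expect_equal(f$lifetimes, truth$lifetimes, tolerance = 0.02)
  for (r in 1:2) {
    cosr <- sum(f$B[, r] * truth$spectra[, r]) /
      sqrt(sum(f$B[, r]^2) * sum(truth$spectra[, r]^2))
    expect_gte(cosr, 0.99)
  }
  expect_false(f$degenerate)
  # spectra are non-negative with unit trapezoidal area
  areas <- apply(f$B, 2, function(b)
    chelatherm:::.trapz(cube$wavelength, b))
  expect_equal(areas, rep(1, 2), tolerance = 1e-8)
  expect_true(all(f$B >= 0))
  expect_true(all(f$concentration_profiles >= 0))
})

test_that("speciation-linked fit recovers log beta and agrees with the
           profile route", {
  cube <- small_cube(log_beta = 12.9, snr = 50, seed = 11)
  sch <- macropa_scheme()
  sp <- list(eu_ml(12.9))
  linked <- parafac_fit(cube, 2, "speciation", scheme = sch, species = sp,
                        seed = 1)
  expect_lt(abs(linked$log_beta - 12.9), 0.1)
  free <- parafac_fit(cube, 2, "free", seed = 1)
  prof <- fit_logK_from_profiles(free$concentration_profiles, sch,
                                 cube$metal_total, cube$ligand_total,
                                 cube$pH, sp, n_mc = 0)
  expect_lt(abs(linked$log_beta - prof$log_beta), 0.05)
})

test_that("profile log beta fit: self-consistency, coverage, degeneracy", {
  sch <- macropa_scheme()
  sp <- list(eu_ml(13.0))
  L <- seq(0, 112e-6, length.out = 12)
  P <- chelatherm:::.solve_series_conc(
    rep(10e-6, 12), L, log10_binding_polynomial(sch, 3.5), sp)
  # exact profiles: recovered within 1e-3
  f0 <- fit_logK_from_profiles(P, sch, rep(10e-6, 12), L, 3.5, sp,
                               n_mc = 0)
  expect_lt(abs(f0$log_beta - 13.0), 1e-3)
  expect_false(f0$pinned)
  # 3% noise: truth inside the Monte Carlo interval
  set.seed(77)
  Pn <- pmax(P + matrix(rnorm(length(P), 0, 0.03 * max(P)), nrow(P)), 0)
  fn <- fit_logK_from_profiles(Pn, sch, rep(10e-6, 12), L, 3.5, sp,
                               n_mc = 100, seed = 5)
  expect_gte(13.0, fn$mc_interval["lower", 1] - 0.1)
  expect_lte(13.0, fn$mc_interval["upper", 1] + 0.1)
  # flat profiles (no complexation signal): pinned-bound warning
  flat <- cbind(rep(1e-5, 12), rep(0, 12))
  expect_warning(
    fit_logK_from_profiles(flat, sch, rep(10e-6, 12), L, 3.5, sp,
                           n_mc = 0),
    "pinned")
})
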