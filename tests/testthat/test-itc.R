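test_that("overflow cell totals match the incremental-mixing oracle", {
  sched <- injection_schedule(injection_volumes = rep(2e-6, 19),
                              syringe_capacity = 40e-6)
  # i = 0: nothing injected
  t0 <- cell_totals_after_injection(sched, 0, n_factor = 0.9)
  expect_equal(unname(t0[1, ]), c(0.9 * 50e-6, 0))
  # first-order expansion for small injected volume
  tiny <- injection_schedule(injection_volumes = 1e-9)
  t1 <- cell_totals_after_injection(tiny, 1)
  expect_equal(unname(t1[1, "ligand_total"]), 500e-6 * 1e-9 / 200e-6,
               tolerance = 1e-4)
  # full 19 x 2 uL series against stepwise mixing, <= 0.5% relative
  oracle <- oracle_cell_totals(200e-6, 50e-6, 500e-6, rep(2e-6, 19))
  model <- cell_totals_after_injection(sched, 0:19)
  expect_equal(model[, 1], oracle[, 1], tolerance = 5e-3)
  expect_equal(model[-1, 2], oracle[-1, 2], tolerance = 5e-3)
  expect_error(cell_totals_after_injection(sched, 20), "out of range")
})

test_that("zero enthalpy gives pure dilution offsets", {
  m <- itc_model(eu_ml(), delta_H = 0, q_dil = 1.7)
  q <- predict_injection_heats(m, injection_schedule(), macropa_scheme(),
                               3.5)
  expect_equal(q, rep(1.7, 19))
})

test_that("stoichiometric limit: constant heat per mole of injected ligand", {
  # huge constant: every injected ligand is complexed immediately
  sched <- injection_schedule(injection_volumes = rep(1e-6, 10))
  m <- itc_model(complex_species(1, 1, 25), delta_H = 20e3)
  q <- predict_injection_heats(m, sched, protolysis_scheme(), 7)
  moles <- sched$syringe_conc * sched$injection_volumes
  q_expected <- 20e3 * moles * 1e6     # uJ, ignoring displaced-volume terms
  expect_equal(q / q_expected, rep(1, 10), tolerance = 0.06)
})

test_that("predicted heats match the fine-bookkeeping oracle to 0.1%", {
  sched <- injection_schedule()
  sp <- list(eu_ml(13.0), complex_species(2, 1, 16.5, "Eu2L"))
  dH <- c(20e3, 6e3)
  m <- itc_model(sp, dH)
  q <- predict_injection_heats(m, sched, macropa_scheme(), 3.6)
  q_oracle <- oracle_injection_heats(sched, macropa_pka, 3.6,
                                     data.frame(m = c(1, 2), l = c(1, 1),
                                                log_beta = c(13.0, 16.5)),
                                     dH, n_sub = 10)
  expect_lt(max(abs(q - q_oracle)) / max(abs(q)), 1e-3)
})

test_that("background subtraction is elementwise and validated", {
  s <- thermogram(c(3, 2, 1), 3.5, "s")
  b <- thermogram(c(1, 1, 1), 3.5, "b", is_blank = TRUE)
  d <- subtract_background(s, b)
  expect_equal(d$heats, c(2, 1, 0))
  expect_false(d$is_blank)
  expect_equal(subtract_background(s, s)$heats, rep(0, 3))
  expect_error(subtract_background(s, thermogram(1:2, 3.5)), "lengths")
  # constant-offset sample minus matching blank equals the no-offset model
  d1 <- gen_itc_dataset(q_dil = 2, noise_sd = 0, seed = 3)
  corr <- subtract_background(d1$sample, d1$blank)
  m0 <- itc_model(eu_ml(13.0), 20e3, q_dil = 0)
  expect_equal(corr$heats,
               predict_injection_heats(m0, d1$schedule, macropa_scheme(),
                                       3.5),
               tolerance = 1e-12)
})

test_that("unit conversion uses 4.184 J/cal", {
  expect_equal(ucal_to_uJ(1), 4.184)
})

test_that("energy bookkeeping and sign invariants hold", {
  sched <- injection_schedule()
  sch <- macropa_scheme()
  sp <- list(eu_ml(13.0))
  conc <- chelatherm:::.itc_complex_conc(sched, sch, sp, 3.5, 1)
  Qc <- conc * sched$cell_volume * 1e6 * 20e3
  # telescoping without the displaced-heat term
  expect_equal(unname(sum(diff(Qc[, 1]))),
               unname(sched$cell_volume * 20e3 * conc[20, 1] * 1e6))
  # flipping every dH flips every heat exactly
  m_pos <- itc_model(sp, 20e3); m_neg <- itc_model(sp, -20e3)
  expect_equal(predict_injection_heats(m_pos, sched, sch, 3.5),
               -predict_injection_heats(m_neg, sched, sch, 3.5))
})

test_that("endo/exothermic phenomenology: lanthanide-like vs Pb-like", {
  sch <- macropa_scheme()
  q_eu <- predict_injection_heats(itc_model(eu_ml(13.0), 20e3),
                                  injection_schedule(), sch, 3.5)
  q_pb <- predict_injection_heats(itc_model(complex_species(1, 1, 18.5),
                                            -30e3),
                                  injection_schedule(), sch, 2)
  expect_true(all(q_eu > 0))
  expect_true(all(q_pb < 0))
  # Pb at pH 2 is sharper: near-rectangular decay past equivalence
  expect_gt(abs(q_pb[2]), 0.9 * max(abs(q_pb)))
})

test_that("noise-free global fit recovers the truth", {
  d <- gen_itc_dataset(seed = 42)
  corr <- subtract_background(d$sample, d$blank)
  fit <- fit_itc(corr, d$schedule, macropa_scheme(), list(eu_ml(13.0)), 3.5)
  expect_lt(abs(fit$log_betas - 13.0), 0.01)
  expect_lt(abs(fit$delta_H - 20e3) / 20e3, 0.01)
  expect_equal(fit$n_factors, 1, tolerance = 0.01)
  expect_lt(fit$rms, 1e-6)
  expect_false(fit$low_c)
})

test_that("nested-model comparison prefers the generating model", {
  # two replicate datasets fitted globally: the spare 2:1 species has
  # enough shared data to be driven to a null contribution
  d1 <- gen_itc_dataset(noise_sd = 0.2, seed = 17)
  d2 <- gen_itc_dataset(noise_sd = 0.2, seed = 18)
  corr <- list(subtract_background(d1$sample, d1$blank),
               subtract_background(d2$sample, d2$blank))
  scheds <- list(d1$schedule, d2$schedule)
  sch <- macropa_scheme()
  fit1 <- fit_itc(corr, scheds, sch, list(eu_ml(13.0)), 3.5)
  fit2 <- suppressWarnings(
    fit_itc(corr, scheds, sch,
            list(eu_ml(13.0), complex_species(2, 1, 16.5, "M2L")), 3.5))
  expect_lte(fit1$rms / fit2$rms, 1.05)
  # the 2:1 species is statistically consistent with zero: dropping it
  # barely changes the misfit, which the fitter flags
  expect_true(fit2$underdetermined)
  expect_false(fit1$underdetermined)
  # and the shared constant stays at the truth
  expect_lt(abs(fit2$log_betas[1] - 13.0), 0.3)
})

test_that("Monte Carlo intervals: zero-noise collapse and determinism", {
  d <- gen_itc_dataset(seed = 42)
  corr <- subtract_background(d$sample, d$blank)
  fit <- fit_itc(corr, d$schedule, macropa_scheme(), list(eu_ml(13.0)), 3.5)
  mc1 <- monte_carlo_errors(fit, n_reps = 60, seed = 9)
  mc2 <- monte_carlo_errors(fit, n_reps = 60, seed = 9)
  expect_identical(mc1$intervals, mc2$intervals)
  # rms ~ 0 so interval widths collapse
  widths <- mc1$intervals["upper", ] - mc1$intervals["lower", ]
  expect_lt(widths[["log_beta_1"]], 1e-4)
  # intervals bracket the point estimate
  expect_lte(mc1$intervals["lower", "log_beta_1"], fit$log_betas[1])
  expect_gte(mc1$intervals["upper", "log_beta_1"], fit$log_betas[1])
  expect_warning(monte_carlo_errors(fit, n_reps = 10, seed = 1),
                 "n_reps")
})

test_that("low c-value is flagged and widens the intervals", {
  # weak conditional affinity: Eu-like constant probed at pH 2.6
  d_lo <- gen_itc_dataset(pH = 2.6, noise_sd = 0.3, seed = 21)
  fit_lo <- fit_itc(subtract_background(d_lo$sample, d_lo$blank),
                    d_lo$schedule, macropa_scheme(), list(eu_ml(13.0)), 2.6)
  expect_true(fit_lo$low_c)
  d_hi <- gen_itc_dataset(pH = 3.5, noise_sd = 0.3, seed = 21)
  fit_hi <- fit_itc(subtract_background(d_hi$sample, d_hi$blank),
                    d_hi$schedule, macropa_scheme(), list(eu_ml(13.0)), 3.5)
  expect_false(fit_hi$low_c)
  mc_lo <- monte_carlo_errors(fit_lo, n_reps = 60, seed = 4)
  mc_hi <- monte_carlo_errors(fit_hi, n_reps = 60, seed = 4)
  w_lo <- diff(mc_lo$intervals[, "log_beta_1"])
  w_hi <- diff(mc_hi$intervals[, "log_beta_1"])
  expect_gt(w_lo, w_hi)
})
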