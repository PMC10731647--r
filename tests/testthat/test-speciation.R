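test_that("protonation betas are cumulative sums in protonation order", {
  expect_equal(protonation_betas(protolysis_scheme(7.00)), 7.00)
  expect_equal(protonation_betas(protolysis_scheme(macropa_pka)),
               c(7.73, 14.53, 17.66, 20.06))
  expect_identical(protonation_betas(protolysis_scheme()), numeric())
  expect_error(protolysis_scheme(c(3, 2)), "most acidic first")
})

test_that("binding polynomial matches direct evaluation and its limits", {
  sch <- macropa_scheme()
  expect_equal(binding_polynomial(protolysis_scheme(), 7), 1.0)
  expect_equal(binding_polynomial(sch, 14), 1.0, tolerance = 1e-5)
  # direct term-by-term evaluation at several pH values
  for (pH in c(1, 3.5, 5, 8, 11)) {
    expect_equal(binding_polynomial(sch, pH), oracle_alpha(macropa_pka, pH),
                 tolerance = 1e-12)
    expect_equal(log10_binding_polynomial(sch, pH),
                 log10(oracle_alpha(macropa_pka, pH)), tolerance = 1e-12)
  }
  expect_equal(log10_binding_polynomial(sch, 3.5), 7.7, tolerance = 0.01)
  expect_gte(binding_polynomial(sch, 2), 1)
})

test_that("conditional logK subtracts the binding polynomial and round-trips", {
  sch <- macropa_scheme()
  expect_equal(conditional_logK(protolysis_scheme(), 13.0, 4.2), 13.0)
  expect_equal(conditional_logK(sch, 13.0, 3.5), 5.3, tolerance = 0.02)
  expect_gt(conditional_logK(sch, 13.0, 5.0), conditional_logK(sch, 13.0, 3.5))
  # exact round trip at assorted pH
  for (pH in c(2, 3.5, 6, 9))
    expect_identical(conditional_logK(sch, 13.0, pH) +
                       log10_binding_polynomial(sch, pH), 13.0)
})

test_that("degenerate speciation corners are exact", {
  sch <- macropa_scheme()
  # no species: free metal equals the total
  r <- solve_speciation(equilibrium_conditions(10e-6, 0, 7), sch)
  expect_equal(r$free_metal, 10e-6)
  expect_length(r$complexes, 0)
  # no ligand: complexes vanish
  r <- solve_speciation(equilibrium_conditions(10e-6, 0, 7), sch,
                        list(eu_ml()))
  expect_equal(unname(r$complexes), 0)
  expect_error(equilibrium_conditions(-1e-6, 0, 7), "non-negative")
  expect_error(equilibrium_conditions(1e-6, 0, 15), "pH")
})

test_that("solver matches the nested-bisection oracle on the worked system", {
  sch <- macropa_scheme()
  r <- solve_speciation(equilibrium_conditions(10e-6, 10e-6, 3.5), sch,
                        list(eu_ml(13.0)))
  o <- oracle_speciation(10e-6, 10e-6, macropa_pka, 3.5,
                         data.frame(m = 1, l = 1, log_beta = 13.0))
  expect_equal(r$free_metal, o$free_metal, tolerance = 1e-8)
  expect_equal(r$free_ligand, o$free_ligand, tolerance = 1e-8)
  expect_equal(unname(r$complexes), o$complexes, tolerance = 1e-8)
  expect_lt(max(abs(r$mass_balance_residuals)), 1e-10)
})

test_that("mass balances close to 1e-10 relative on random systems", {
  set.seed(99)
  for (rep in 1:25) {
    npk <- sample(0:4, 1)
    sch <- protolysis_scheme(sort(runif(npk, 1, 12)))
    sp <- list(complex_species(1, 1, runif(1, 3, 20)))
    if (runif(1) < 0.4)
      sp <- c(sp, list(complex_species(2, 1, runif(1, 6, 25))))
    M <- 10^runif(1, -7, -3); L <- 10^runif(1, -7, -3)
    pH <- runif(1, 1, 11)
    r <- solve_speciation(equilibrium_conditions(M, L, pH), sch, sp)
    expect_lt(max(abs(r$mass_balance_residuals)), 1e-10)
    # recompute totals from the reported concentrations
    alpha <- oracle_alpha(sch$pKa, pH)
    mj <- vapply(sp, `[[`, integer(1), "m")
    lj <- vapply(sp, `[[`, integer(1), "l")
    M_re <- r$free_metal + sum(mj * r$complexes)
    L_re <- r$free_ligand * alpha + sum(lj * r$complexes)
    expect_equal(M_re, M, tolerance = 1e-10)
    expect_equal(L_re, L, tolerance = 1e-10)
  }
})

test_that("titration speciation is elementwise solve_speciation and monotone", {
  sch <- macropa_scheme()
  sp <- list(eu_ml(13.0))
  L <- seq(0, 112e-6, length.out = 12)
  sched <- lapply(L, function(x) equilibrium_conditions(10e-6, x, 3.5))
  res <- titration_speciation(sched, sch, sp)
  # single-step equivalence
  one <- solve_speciation(sched[[5]], sch, sp)
  expect_equal(res[[5]]$free_metal, one$free_metal)
  expect_equal(res[[5]]$complexes, one$complexes)
  # complexed fraction non-decreasing along the ligand titration
  frac <- vapply(res, function(r) sum(r$complexes) / 10e-6, numeric(1))
  expect_true(all(diff(frac) >= -1e-12))
  # concave beyond the equivalence point (L > M_tot)
  post <- frac[L > 10e-6]
  expect_true(all(diff(diff(post)) <= 1e-12))
})

test_that("saturation limit: huge log beta complexes all metal", {
  sch <- macropa_scheme()
  r <- solve_speciation(equilibrium_conditions(10e-6, 20e-6, 7), sch,
                        list(complex_species(1, 1, 30)))
  expect_equal(unname(r$complexes), 10e-6, tolerance = 1e-6)
})

test_that("per-step failures carry the step index", {
  sched <- list(equilibrium_conditions(1e-6, 1e-6, 7))
  expect_error(
    titration_speciation(c(sched, list(structure(
      list(metal_total = -1, ligand_total = 0, pH = 7),
      class = "equilibrium_conditions"))), macropa_scheme(), list(eu_ml())),
    "step 2")
})
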