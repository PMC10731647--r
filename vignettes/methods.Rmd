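---
title: "Models and numerical methods in chelatherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in chelatherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`chelatherm` determines the solution thermodynamics of metal complexes
with polyprotic macrocyclic chelators from three titration experiments —
NMR (pKa), isothermal titration calorimetry (log K, ΔH, n) and
time-resolved laser-induced luminescence (log K, lifetimes, hydration
numbers) — tied together by one mass-action speciation model. This
vignette states the models, their assumptions, the tunable parameters and
the numerical choices, and what the synthetic-data tests do and do not
establish.

## 1. The speciation model

All stages share a single equilibrium description. For a ligand L with
`p` dissociable protons and complexes MₘLₗ:

* **Protonation.** Stepwise pKa values (most acidic first) convert to
  cumulative protonation constants log β_H,i = Σ of the `i` most basic
  pKa values. The side-reaction coefficient (binding polynomial)
  α_L(H) = 1 + Σᵢ β_H,i [H⁺]ⁱ collects all protonated ligand forms; the
  conditional constant at a buffered pH is
  log K′ = log K − log₁₀ α_L(H). Working at reduced pH deliberately
  shrinks K′ of a high-affinity ligand into the window where free and
  bound metal coexist measurably — the central experimental trick the
  package supports.
* **Mass balances.** With [H⁺] fixed at 10^−pH (pH-stat / buffered
  practice; no proton balance is solved),
  M_tot = [M] + Σⱼ mⱼ βⱼ [M]^mⱼ [L]^lⱼ and
  L_tot = [L] α_L(H) + Σⱼ lⱼ βⱼ [M]^mⱼ [L]^lⱼ.
* **Conditionality.** All constants are conditional at the stated medium
  (0.1 M NaCl, 25 °C). No activity-coefficient model is applied; do not
  mix constants across ionic strengths.
* **Species lists.** Generic (m, l) species are representable; the
  default models use 1:1 (and optionally 2:1 metal:ligand) complexes and
  no protonated or hydroxo ternary species, which mirrors the systems the
  package targets.

**Numerics.** The solver works in x = (log₁₀[M], log₁₀[L]): free
concentrations span many decades and log coordinates preserve positivity
and conditioning. A damped Newton iteration with the analytic 2×2
Jacobian (step clamp 2 decades, halving line search) converges to scaled
residuals ≤ 1e−12 in a handful of iterations; on failure the package
falls back to nested bisection (ligand balance inner, metal balance
outer — both monotone). Titration series are solved with warm starts
from the previous step. The test suite checks 200 random systems against
an independently written nested-bisection oracle to 1e−8 relative
(observed agreement ~1e−12).

## 2. NMR pKa stage

The fast-exchange chemical shift of a probe nucleus is modelled as a sum
of sigmoids, δ(pD) = δ₀ + Σₖ Aₖ / (1 + 10^{sₖ(pDₖ − pD)}); each
inflection pDₖ estimates a pKa on the pD scale, corrected to the aqueous
scale by subtracting 0.4 (the same constant that relates a glass
electrode reading in D₂O to pD).

Choices and rationale:

* **Slopes sₖ default to 1** — a one-proton transition in fast exchange
  has unit Hill slope. `free_slopes = TRUE` releases them, for probes
  with coupled transitions; the recovery tests exercise both modes.
* **Initialisation** is deterministic: inflection guesses are peaks of
  the numerical derivative of a running-median-smoothed shift curve.
  With slopes fixed, δ₀ and the Aₖ are linear and profiled out by least
  squares, so only the inflections are searched (Nelder–Mead with a
  restart polish; golden-section for a single transition).
* **Degenerate input** (shift range below 3× a second-difference noise
  estimate) raises an error rather than returning a meaningless fit.
* **Reported uncertainty** per merged transition is
  max(covariance σ, 0.15): the pH electrode, not the regression,
  dominates the real error budget.
* **Probe merging** (`assemble_scheme`): inflections from different
  probes within 0.3 pD units are pooled by inverse-variance weighting;
  probes claiming the same transition but > 0.3 apart raise an error.

## 3. ITC stage

For a perfusion (overflow) cell of volume V₀, cumulative injected volume
ΔVᵢ gives the standard displaced-volume totals
Mᵢ = n·M₀ (1 − ΔVᵢ/2V₀)/(1 + ΔVᵢ/2V₀),
Lᵢ = L_syr (ΔVᵢ/V₀)/(1 + ΔVᵢ/2V₀); these are the Padé form of the
continuous-displacement exponential and agree with a stepwise mixing
simulation to ≲0.3% over a 40 µL program. The cumulative heat content is
Q_i = V₀ Σⱼ ΔHⱼ [MₘLₗ]ᵢ and the observed heat of injection i is
qᵢ = (Qᵢ − Qᵢ₋₁) + (vᵢ/V₀)(Qᵢ + Qᵢ₋₁)/2 + q_dil — the middle term
credits heat carried out with liquid displaced at cell composition.
Endothermic is positive. Heats are handled in µJ; µcal input converts
with 4.184 J/cal.

Fitting choices:

* **Variable projection.** For fixed (log β, n) the model is linear in
  the ΔHⱼ (shared across datasets) and per-dataset q_dil, which are
  solved by least squares inside the objective; the outer Nelder–Mead
  search only sees (log β, n). This removes the dominant source of
  multimodality and makes noise-free recovery exact to the optimizer
  tolerance.
* **Multistart.** A coarse grid scan (±4 around the seeded log β, step
  1) seeds five deterministic starts at offsets {0, ±1.5, ±3}, plus the
  user's seed itself. Heat curves are multimodal in K at high c-values;
  the grid scan is cheap insurance.
* **Active fraction n ∈ [0.5, 1.5].** n is a concentration-accuracy
  correction, not a stoichiometry. Left unbounded, an M₂L species with
  n ≈ 2 re-labels a 1:1 system almost exactly (a flat compensation
  ridge); the bound keeps the fit on the physical branch.
* **q_dil is fitted even after blank subtraction** — residual offsets
  from imperfect blank matching are routine.
* **Identifiability diagnostics.** `low_c` fires when the fitted
  c-value (n·M₀·K′) < 1 *or* when shifting log β by ±0.5 (with linear
  parameters re-solved) changes the misfit by < 10% — the latter catches
  degenerate fits whose point estimate escaped to a strong-binding
  limit. `underdetermined` fires when dropping a species and refitting
  raises the SSE by < 5%: on a near-flat ridge the point amplitude of a
  spare species is meaningless, but the likelihood ratio is not.
* **First-injection exclusion** is available (`exclude_first`) but off
  by default.

## 4. TRLFS / PARAFAC stage

A titration cube X[s, λ, t] (titration step × emission wavelength × gate
delay) of R emitting species is trilinear:
X ≈ Σ_r C[s,r] B[λ,r] exp(−t/τ_r). The physics enters as constraints:
spectra non-negative with unit trapezoidal area, decays hard-parameterised
as mono-exponentials (each τ_r refit every sweep by a 1-D golden-section
search in log τ, with the species' amplitude profiled out), and the
concentration mode either free non-negative (Lawson–Hanson NNLS per
sample) or replaced by mass-action profiles with log β as the fitted
scalar. All magnitude lives in the concentration mode; the time factor
is 1 at zero delay.

* **Delay schedule.** Gate delays follow the linearly increasing step
  rule: k-th increment a·k µs, cumulative offsets a·k(k+1)/2 on top of an
  initial delay (12 µs, suppressing emission from higher excited
  states). Defaults: a = 7, 21 gates (ambient; 12–1482 µs); a = 15 for
  cryogenic work. The printed range of the source protocol does not
  match any simple cumulative rule exactly, so the schedule is fully
  configurable and generated cubes record their absolute delays in the
  manifest.
* **Initialisation** is deterministic given the seed: spectra from
  non-negativised singular vectors of the wavelength unfolding, τ from
  log-spaced endpoints of the delay span with seed-controlled ±5%
  jitter.
* **Speciation-linked mode** warm-starts from a free decomposition whose
  profiles seed log β via `fit_logK_from_profiles`, then refines log β
  (±0.5 bracket per sweep), per-species brightness (NNLS), spectra and
  lifetimes jointly.
* **Convergence** is declared when the SSE changes by < 1e−8 of the data
  norm (500-sweep cap); factor congruence > 0.98 flags a probably
  over-specified rank. Species are reported in ascending lifetime order.
* **Weighting.** Unweighted least squares, matching common practice; the
  synthetic generator's shot-noise option makes the homoskedastic
  approximation mild at the SNRs tested.
* **Hydration numbers.** n(H₂O) = 1.05/τ − 0.44 (τ in ms) with the
  empirical ±0.5 band attached; strictly decreasing in τ. At ~0.385 ms
  this gives ≈ 2.29 (about two inner-sphere waters); at ~1 ms, 0.61
  (zero or one).

## 5. Monte Carlo uncertainty

All stages use the same parametric scheme: Gaussian noise with σ equal
to the fitted rms is added to the model prediction, each replicate is
refit from the point estimate, and the central 68.3% of replicate
estimates forms the interval. The exact resampling protocol of the
original analyses is not published; parametric noise at the fitted
residual level is the decided stand-in, and its calibration is itself
tested (empirical coverage of the nominal 68.3% interval over 100 outer
replications stays within the binomial band, typically 0.60–0.70 — the
mild undercoverage is the familiar price of estimating σ from the fit).

## 6. The synthetic-data generators

The generators emulate the stated experimental designs: a 1 mM ligand pD
titration (0.8–9.6) read by two probe families with two transitions
each; a 500 µM-ligand-into-50 µM-metal injection program (19 aliquots,
0.5 then 2 µL, 200 µL cell, 40 µL syringe); and a two-species Eu cube
(0–112 µM ligand into 10 µM Eu at pH 3.5, lifetimes 0.109/0.385 ms) on
the ambient delay schedule. Noise-free outputs go through exactly the
consuming module's forward-model code path, so round-trip tests separate
estimator error from model error.

Stated choices that are *package defaults, not measured values*:

* **Eu emission bands** (`eu_band_defaults()`): Gaussian mixtures near
  579/592/616/650/700 nm, the aquo ion dominated by the 592 nm
  magnetic-dipole band and the complex by the hypersensitive 616 nm
  band. No spectral table was available; only band *positions* being
  roughly right matters for the recovery tests.
* **2:1 complex constants** are free synthetic-truth parameters (the
  source analyses fit them but never print them).
* **ΔH = +20 kJ/mol (lanthanide-like) / −30 kJ/mol (Pb-like)** and
  q_dil = 2 µJ are realistic scales chosen once; only their signs are
  anchored in the observed endo/exothermic contrast.
* **TRLFS noise is Poisson by default.** With additive Gaussian noise at
  peak SNR 50, ~26% of cube values fall below zero and clipping to the
  physical range biases the weak (aquo) lifetime 3–4% low at every seed.
  Camera counts are Poisson; with shot noise the recovery is unbiased.
  Clipped Gaussian remains available (`noise_model = "gaussian"`).

What a green test establishes: that the estimators recover known truths
under the stated designs and noise models. What it does not: instrument
systematics (baseline drifts, first-injection artefacts, detector
nonlinearity, spectral wandering), model misspecification (ternary
species, slow kinetics), or pH-electrode bias — the dominant real error
for pKa, which is why the reported pKa uncertainty is floored at 0.15.

## 7. Known limitations

* pH is an external master variable; systems where complexation
  perturbs pH appreciably need an external buffer model.
* Mono-exponential decays only; quenching heterogeneity or
  excited-state kinetics are out of scope.
* The ITC model has no ΔCp or kinetic (injection-spacing) terms.
* The Horrocks relation carries its own ±0.5 systematic band; the
  package reports but cannot reduce it.
* Two-species PARAFAC identifiability assumes distinct lifetimes
  (ratio ≳ 2) and spectra (cosine ≲ 0.9); the rank-degeneracy warning
  (congruence > 0.98) is a guard, not a proof.
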