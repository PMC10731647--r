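# Seeded synthetic-data generators.  Each generator embeds its ground truth
# (and the seed) in a "truth" attribute so recovery tests are self-contained,
# and builds its noise-free signal through the same code path the consuming
# fitter uses, so noise-free outputs match the forward model bit for bit.

#' Generate synthetic NMR pD-titration series
#'
#' Probe shifts follow the (bi)dose-response model with inflections at
#' `pKa + 0.4` on the pD scale (deuterium correction applied in reverse) and
#' unit Hill slopes, plus Gaussian noise.  Probes are assigned consecutive
#' transition pairs: with the default four-step ladder, probe 1 (aromatic)
#' senses the two carboxyl deprotonations and probe 2 (macrocycle) the two
#' ammonium deprotonations.
#'
#' @param pKa truth pKa ladder (aqueous scale), most acidic first; may be
#'   empty (flat series at baseline).
#' @param pD sampling grid (default 0.8 to 9.6 in 0.2 steps, the typical
#'   titration design for a 1 mM ligand in 0.1 M NaCl D2O).
#' @param noise_sd Gaussian shift noise, ppm (default 0).
#' @param seed integer seed (mandatory).
#' @param amplitudes per-transition shift amplitude, ppm (recycled; default
#'   -0.15, upfield on deprotonation).
#' @param baselines per-probe acidic-limit shift, ppm (recycled).
#' @param slopes Hill slopes (default 1).
#' @return list of [nmr_titration_series()] with attribute `truth`.
#' @export
gen_nmr_titration <- function(pKa = c(2.40, 3.13, 6.80, 7.73),
                              pD = seq(0.8, 9.6, by = 0.2),
                              noise_sd = 0, seed,
                              amplitudes = -0.15,
                              baselines = c(7.8, 3.4),
                              slopes = 1) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noise_sd >= 0)
  if (length(pKa) && is.unsorted(pKa)) stop("pKa ladder must be sorted")
  set.seed(seed)
  nt <- length(pKa)
  if (nt == 0L) {
    y <- rep(baselines[1], length(pD)) +
      stats::rnorm(length(pD), 0, noise_sd)
    out <- list(nmr_titration_series("probe_1", pD, y))
    attr(out, "truth") <- list(pKa = numeric(), seed = seed,
                               noise_sd = noise_sd)
    return(out)
  }
  groups <- split(seq_len(nt), ceiling(seq_len(nt) / 2))
  amplitudes <- rep_len(amplitudes, nt)
  slopes <- rep_len(slopes, nt)
  baselines <- rep_len(baselines, length(groups))
  infl_pD <- pKa + 0.4
  probe_names <- if (length(groups) == 2) c("aromatic", "macrocycle") else
    paste0("probe_", seq_along(groups))
  out <- lapply(seq_along(groups), function(g) {
    ix <- groups[[g]]
    y <- .dose_response(pD, baselines[g], amplitudes[ix], infl_pD[ix],
                        slopes[ix])
    y <- y + stats::rnorm(length(pD), 0, noise_sd)
    nmr_titration_series(probe_names[g], pD, y)
  })
  attr(out, "truth") <- list(pKa = pKa, pD_inflections = infl_pD,
                             amplitudes = amplitudes, slopes = slopes,
                             baselines = baselines, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Generate a synthetic ITC dataset (sample + blank)
#'
#' Heats come from [predict_injection_heats()] at the truth parameters plus
#' Gaussian noise; the blank is the constant dilution offset plus noise.
#' Defaults mirror a lanthanide-like titration: 500 uM ligand into 50 uM
#' metal, 19 aliquots, endothermic 1:1 complexation.
#'
#' @param scheme a [protolysis_scheme()] (default: the four-step macropa
#'   ladder).
#' @param species list of [complex_species()] carrying the truth log beta
#'   (default: 1:1 complex, log beta 13).
#' @param delta_H truth molar enthalpies, J/mol (default +20 kJ/mol,
#'   endothermic as observed for lanthanides).
#' @param n_factor truth active fraction (default 1).
#' @param q_dil dilution offset, uJ (default 2).
#' @param pH titration pH (default 3.5).
#' @param schedule an [injection_schedule()] (default geometry).
#' @param noise_sd Gaussian heat noise, uJ (default 0).
#' @param seed integer seed (mandatory).
#' @return list: `sample`, `blank` ([thermogram()]), `schedule`, and `truth`.
#' @export
gen_itc_dataset <- function(scheme = protolysis_scheme(c(2.40, 3.13, 6.80,
                                                         7.73)),
                            species = list(complex_species(1, 1, 13.0,
                                                           "ML")),
                            delta_H = 20e3, n_factor = 1, q_dil = 2,
                            pH = 3.5, schedule = injection_schedule(),
                            noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noise_sd >= 0, length(delta_H) == length(species))
  set.seed(seed)
  model <- itc_model(species, delta_H, n_factor = n_factor, q_dil = q_dil)
  q <- predict_injection_heats(model, schedule, scheme, pH)
  n <- schedule$n_injections
  sample <- thermogram(q + stats::rnorm(n, 0, noise_sd), pH,
                       label = "synthetic sample")
  blank <- thermogram(rep(q_dil, n) + stats::rnorm(n, 0, noise_sd), pH,
                      label = "synthetic blank", is_blank = TRUE)
  list(sample = sample, blank = blank, schedule = schedule,
       truth = list(log_betas = vapply(species, `[[`, numeric(1),
                                       "log_beta"),
                    delta_H = delta_H, n_factor = n_factor, q_dil = q_dil,
                    pH = pH, noise_sd = noise_sd, seed = seed))
}

#' Default Eu(III) emission band parameters (synthetic, not measured)
#'
#' Gaussian-mixture stand-ins for the 5D0 -> 7F0..4 emission bands near
#' 579/592/616/650/700 nm.  The aquo ion is dominated by the magnetic-dipole
#' 592 nm band; the complex by the hypersensitive 616 nm band.  These are
#' package defaults chosen for realism; no measured spectral table underlies
#' them.
#'
#' @return list with per-species data frames (`center`, `width`, `height`).
#' @export
eu_band_defaults <- function() {
  list(
    aquo = data.frame(center = c(579, 592, 616, 650, 700),
                      width = c(2.5, 3.5, 3.5, 3, 4),
                      height = c(0.02, 1.00, 0.35, 0.05, 0.15)),
    complex = data.frame(center = c(579.5, 593, 615.5, 651, 699),
                         width = c(2.5, 4.5, 5.0, 3.5, 6),
                         height = c(0.15, 0.70, 1.60, 0.10, 0.80)))
}

# Gaussian-mixture spectrum on a wavelength grid, unit area
.gaussian_spectrum <- function(wavelength, bands) {
  y <- rep(0, length(wavelength))
  for (i in seq_len(nrow(bands)))
    y <- y + bands$height[i] *
      exp(-0.5 * ((wavelength - bands$center[i]) / bands$width[i])^2)
  y / .trapz(wavelength, y)
}

#' Generate a synthetic TRLFS titration cube
#'
#' Two-species Eu(III) emission cube: intensities are
#' `sum_s brightness_s * conc_s(step) * spectrum_s(lambda) * exp(-t/tau_s)`
#' plus optional Gaussian noise, with concentration profiles from the
#' mass-action speciation at the truth log beta.  The default design mirrors
#' a ligand titration (0 to 112 uM) into 10 uM Eu at pH 3.5 on the ambient
#' gate-delay schedule; truth lifetimes are 0.109 ms (aquo) and 0.385 ms
#' (complex).
#'
#' @param scheme a [protolysis_scheme()].
#' @param species list of [complex_species()] with truth log beta (default:
#'   1:1 complex, log beta 12.9).
#' @param lifetimes truth lifetimes, ms: free metal first, then one per
#'   complex.
#' @param brightness relative emissive scale per species (free metal first).
#' @param wavelength emission grid, nm.
#' @param schedule a [build_delay_schedule()].
#' @param metal_total scalar or per-step metal totals, mol/L.
#' @param ligand_total per-step ligand totals, mol/L.
#' @param pH titration pH.
#' @param snr signal-to-noise ratio at the intensity maximum; `Inf` for
#'   noise-free.
#' @param noise_model `"poisson"` (default; shot noise, the camera's actual
#'   statistic -- the peak is scaled to `snr^2` expected counts so that the
#'   peak SNR equals `snr`) or `"gaussian"` (additive, sigma = max/snr,
#'   clipped at zero).  Zero-clipping of additive noise biases weak
#'   components; prefer the default for recovery studies.
#' @param intensity_scale counts per (mol/L * unit-area spectral density).
#' @param bands band table as from [eu_band_defaults()].
#' @param seed integer seed (mandatory).
#' @return a [trlfs_cube()] with attribute `truth` (including the exact
#'   factor matrices and absolute delays used).
#' @export
gen_trlfs_cube <- function(scheme = protolysis_scheme(c(2.40, 3.13, 6.80,
                                                        7.73)),
                           species = list(complex_species(1, 1, 12.9,
                                                          "EuL")),
                           lifetimes = c(0.109, 0.385),
                           brightness = c(1, 3),
                           wavelength = seq(570, 720, by = 1),
                           schedule = build_delay_schedule(),
                           metal_total = 10e-6,
                           ligand_total = seq(0, 112e-6, length.out = 15),
                           pH = 3.5, snr = Inf,
                           noise_model = c("poisson", "gaussian"),
                           intensity_scale = 1e9,
                           bands = eu_band_defaults(), seed) {
  noise_model <- match.arg(noise_model)
  if (missing(seed)) stop("seed is mandatory")
  R <- length(species) + 1
  stopifnot(length(lifetimes) == R, length(brightness) == R)
  set.seed(seed)
  S <- length(ligand_total)
  metal_total <- rep_len(metal_total, S)
  sched <- lapply(seq_len(S), function(s)
    equilibrium_conditions(metal_total[s], ligand_total[s], pH))
  P <- speciation_profiles(titration_speciation(sched, scheme, species))
  B <- cbind(.gaussian_spectrum(wavelength, bands$aquo),
             if (R > 1) vapply(seq_len(R - 1), function(j)
               .gaussian_spectrum(wavelength, bands$complex),
               numeric(length(wavelength))))
  t_ms <- schedule$delays / 1000
  D <- exp(outer(-t_ms, 1 / lifetimes))
  C <- sweep(P, 2, brightness, "*") * intensity_scale
  X1 <- .trilinear_unfold1(C, B, D)
  X <- array(X1, dim = c(S, length(wavelength), schedule$n_gates))
  if (is.finite(snr)) {
    sigma <- max(X) / snr
    if (noise_model == "poisson") {
      # shot noise: peak scaled to snr^2 expected counts, rescaled back
      scale <- snr^2 / max(X)
      X <- array(stats::rpois(length(X), X * scale) / scale, dim = dim(X))
    } else {
      X <- X + array(stats::rnorm(length(X), 0, sigma), dim = dim(X))
      X[X < 0] <- 0
    }
  } else sigma <- 0
  cube <- trlfs_cube(X, wavelength, schedule, metal_total, ligand_total, pH)
  attr(cube, "truth") <- list(
    log_betas = vapply(species, `[[`, numeric(1), "log_beta"),
    lifetimes = lifetimes, brightness = brightness, spectra = B,
    concentration_profiles = C, profiles_molar = P, noise_sd = sigma,
    delays_us = schedule$delays, seed = seed)
  cube
}
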