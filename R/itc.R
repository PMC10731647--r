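#' ITC injection schedule and cell geometry
#'
#' Describes a perfusion (overflow) cell titration: fixed active cell volume,
#' syringe titrant concentration, initial cell metal concentration and the
#' per-injection volumes.  The default mirrors a common microcalorimeter
#' setup: 200 uL cell, 40 uL syringe, 500 uM ligand titrated into 50 uM metal
#' in 19 aliquots (one 0.5 uL pre-injection then 2 uL steps), 150 s apart.
#'
#' @param cell_volume active cell volume V0, litres.
#' @param syringe_conc ligand concentration in the syringe, mol/L.
#' @param cell_metal_conc initial metal concentration in the cell, mol/L.
#' @param injection_volumes per-injection volumes, litres.
#' @param spacing injection spacing, seconds (metadata).
#' @param syringe_capacity total syringe volume, litres.
#' @return object of class `injection_schedule`.
#' @export
injection_schedule <- function(cell_volume = 200e-6,
                               syringe_conc = 500e-6,
                               cell_metal_conc = 50e-6,
                               injection_volumes = c(0.5e-6, rep(2e-6, 18)),
                               spacing = 150,
                               syringe_capacity = 40e-6) {
  if (any(injection_volumes <= 0) || cell_volume <= 0)
    stop("all volumes must be positive")
  if (sum(injection_volumes) > syringe_capacity + 1e-12)
    stop("cumulative injected volume exceeds syringe capacity")
  structure(list(cell_volume = cell_volume, syringe_conc = syringe_conc,
                 cell_metal_conc = cell_metal_conc,
                 injection_volumes = injection_volumes, spacing = spacing,
                 syringe_capacity = syringe_capacity,
                 n_injections = length(injection_volumes)),
            class = "injection_schedule")
}

#' Per-injection integrated heats
#'
#' @param heats integrated heat per injection, micro-joules (endothermic
#'   positive).
#' @param pH solution pH.
#' @param label free-text label.
#' @param is_blank TRUE for a background (no metal) measurement.
#' @return object of class `thermogram`.
#' @export
thermogram <- function(heats, pH, label = "", is_blank = FALSE) {
  if (any(!is.finite(heats))) stop("heats must be finite")
  structure(list(heats = as.numeric(heats), pH = pH, label = label,
                 is_blank = isTRUE(is_blank)),
            class = "thermogram")
}

#' Cell totals after injection i (overflow perfusion-cell model)
#'
#' With cumulative injected volume `dV_i`, the standard overflow equations
#' give
#' \deqn{M_i = n\,M_0 \frac{1 - dV_i/2V_0}{1 + dV_i/2V_0}, \qquad
#'       L_i = L_{syr} \frac{dV_i/V_0}{1 + dV_i/2V_0}.}
#' `i = 0` is the pre-injection state.
#'
#' @param schedule an [injection_schedule()].
#' @param i injection index, 0..n_injections; vectorised.
#' @param n_factor active-fraction multiplier on the cell metal (default 1).
#' @return matrix with columns `metal_total`, `ligand_total` (mol/L), one row
#'   per requested index.
#' @export
cell_totals_after_injection <- function(schedule, i, n_factor = 1) {
  stopifnot(inherits(schedule, "injection_schedule"))
  if (any(i < 0 | i > schedule$n_injections))
    stop("injection index out of range 0..", schedule$n_injections)
  cum <- c(0, cumsum(schedule$injection_volumes))
  dV <- cum[i + 1]
  V0 <- schedule$cell_volume
  denom <- 1 + dV / (2 * V0)
  M <- n_factor * schedule$cell_metal_conc * (1 - dV / (2 * V0)) / denom
  L <- schedule$syringe_conc * (dV / V0) / denom
  cbind(metal_total = M, ligand_total = L)
}

#' Thermodynamic model for an ITC forward calculation
#'
#' @param species list of [complex_species()] (their `log_beta` fields are the
#'   formation constants used).
#' @param delta_H molar reaction enthalpy per species, J/mol (endothermic
#'   positive), parallel to `species`.
#' @param n_factor active-fraction multiplier on the cell metal.
#' @param q_dil constant per-injection dilution offset, micro-joules.
#' @return object of class `itc_model`.
#' @export
itc_model <- function(species, delta_H, n_factor = 1, q_dil = 0) {
  if (inherits(species, "complex_species")) species <- list(species)
  stopifnot(length(species) == length(delta_H), n_factor > 0)
  structure(list(species = species, delta_H = as.numeric(delta_H),
                 n_factor = n_factor, q_dil = q_dil),
            class = "itc_model")
}

# internal: complex-concentration matrix along the injections.
# rows = injection state 0..n, columns = species.
.itc_complex_conc <- function(schedule, scheme, species, pH, n_factor) {
  n <- schedule$n_injections
  totals <- cell_totals_after_injection(schedule, 0:n, n_factor)
  log_alpha <- log10_binding_polynomial(scheme, pH)
  conc <- .solve_series_conc(totals[, 1], totals[, 2], log_alpha, species)
  conc[, -1, drop = FALSE]
}

# internal: per-injection design matrix X (uJ per unit delta_H in J/mol):
# q_i = sum_j dH_j * X[i, j] + q_dil
.itc_design <- function(schedule, scheme, species, pH, n_factor) {
  conc <- .itc_complex_conc(schedule, scheme, species, pH, n_factor)
  V0 <- schedule$cell_volume
  v <- schedule$injection_volumes
  n <- schedule$n_injections
  # cumulative heat per unit dH, uJ: V0 * [complex] * 1e6
  Qc <- conc * V0 * 1e6
  X <- (Qc[2:(n + 1), , drop = FALSE] - Qc[1:n, , drop = FALSE]) +
    (v / V0) * (Qc[2:(n + 1), , drop = FALSE] + Qc[1:n, , drop = FALSE]) / 2
  X
}

#' Forward-model per-injection ITC heats from speciation
#'
#' The cumulative heat content of the cell after injection i is
#' `Q_i = V0 * sum_j dH_j [complex_j]_i` (totals from the overflow model).
#' The observed heat of injection i adds the midpoint correction for liquid
#' displaced at cell composition during the injection and the constant
#' dilution offset:
#' `q_i = (Q_i - Q_{i-1}) + (v_i/V0)(Q_i + Q_{i-1})/2 + q_dil`.
#' Sign convention: endothermic positive.
#'
#' @param model an [itc_model()].
#' @param schedule an [injection_schedule()].
#' @param scheme a [protolysis_scheme()].
#' @param pH fixed pH of the titration.
#' @return numeric vector of per-injection heats, micro-joules.
#' @export
predict_injection_heats <- function(model, schedule, scheme, pH) {
  stopifnot(inherits(model, "itc_model"),
            inherits(schedule, "injection_schedule"))
  X <- .itc_design(schedule, scheme, model$species, pH, model$n_factor)
  drop(X %*% model$delta_H) + model$q_dil
}

#' Subtract a background (dilution) thermogram from a sample thermogram
#'
#' @param sample,blank [thermogram()] objects on the same schedule.
#' @return corrected [thermogram()] (`is_blank = FALSE`).
#' @export
subtract_background <- function(sample, blank) {
  stopifnot(inherits(sample, "thermogram"), inherits(blank, "thermogram"))
  if (length(sample$heats) != length(blank$heats))
    stop("sample and blank thermograms have different lengths")
  thermogram(sample$heats - blank$heats, pH = sample$pH,
             label = paste0(sample$label, " (background-subtracted)"),
             is_blank = FALSE)
}

#' Convert micro-calories to micro-joules
#' @param ucal heats in micro-calories.
#' @return heats in micro-joules (1 cal = 4.184 J).
#' @export
ucal_to_uJ <- function(ucal) ucal * 4.184

# internal: inner (linear) solve of dH (shared) + q_dil (per dataset) given
# outer parameters; returns SSE, coefficients and fitted values.
.itc_inner <- function(log_betas, n_factors, thermograms, schedules, scheme,
                       species, pHs, fit_q_dil = TRUE) {
  nd <- length(thermograms)
  ns <- length(species)
  sp <- lapply(seq_len(ns), function(j) {
    s <- species[[j]]; s$log_beta <- log_betas[j]; s
  })
  Xs <- vector("list", nd)
  for (d in seq_len(nd)) {
    Xs[[d]] <- tryCatch(
      .itc_design(schedules[[d]], scheme, sp, pHs[d], n_factors[d]),
      error = function(e) NULL)
    if (is.null(Xs[[d]])) return(list(sse = Inf))
  }
  y <- unlist(lapply(thermograms, `[[`, "heats"))
  X <- do.call(rbind, Xs)
  if (fit_q_dil) {
    for (d in seq_len(nd)) {
      z <- matrix(0, nrow(X), 1)
      z[rep(seq_len(nd), vapply(Xs, nrow, 1L)) == d, 1] <- 1
      X <- cbind(X, z)
    }
  }
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(sse = sum(fit$residuals^2),
       delta_H = unname(cf[seq_len(ns)]),
       q_dil = if (fit_q_dil) unname(cf[ns + seq_len(nd)]) else rep(0, nd),
       fitted = drop(X %*% cf), design = Xs)
}

#' Globally fit ITC thermograms on a speciation basis
#'
#' Least-squares fit of predicted versus observed per-injection heats over
#' formation constants (shared across datasets), per-species molar enthalpies
#' (shared), a per-dataset active fraction `n` and a per-dataset residual
#' dilution offset `q_dil`.  The pKa scheme is fixed (taken from the NMR
#' stage), never refit.  Enthalpies and offsets enter the model linearly and
#' are profiled out (variable projection); the outer search over
#' `(log beta, n)` runs from five deterministic starts around a coarse
#' grid-scan seed of the primary constant.
#'
#' @param thermograms a [thermogram()] or list of them (background-subtracted
#'   or raw; `q_dil` absorbs residual offsets).
#' @param schedules an [injection_schedule()] or list parallel to
#'   `thermograms`.
#' @param scheme a [protolysis_scheme()] (fixed).
#' @param species list of [complex_species()]; their `log_beta` fields seed
#'   the search.
#' @param pH scalar or vector of dataset pH values.
#' @param exclude_first drop injection 1 from the residual (common ITC
#'   practice; default FALSE).
#' @param n_start initial active fraction (default 1).
#' @param n_bounds allowed range of the active fraction (default
#'   `c(0.5, 1.5)`).  An active fraction is a concentration-accuracy
#'   correction, not a stoichiometry; bounding it keeps the fit out of
#'   compensated modes in which an `n` near an integer multiple re-labels the
#'   complex stoichiometry (e.g. `n ~ 2` with a 2:1 species imitating a 1:1
#'   system).
#' @return object of class `itc_fit`: `log_betas`, `delta_H` (J/mol),
#'   `n_factors`, `q_dil` (uJ), `rms` (uJ), `fitted`, `observed`, flags
#'   `low_c` and `underdetermined`, plus the inputs.
#' @export
fit_itc <- function(thermograms, schedules, scheme, species, pH,
                    exclude_first = FALSE, n_start = 1,
                    n_bounds = c(0.5, 1.5)) {
  if (inherits(thermograms, "thermogram")) thermograms <- list(thermograms)
  if (inherits(schedules, "injection_schedule"))
    schedules <- rep(list(schedules), length(thermograms))
  if (inherits(species, "complex_species")) species <- list(species)
  stopifnot(length(thermograms) >= 1,
            length(schedules) == length(thermograms))
  pHs <- rep_len(pH, length(thermograms))
  nd <- length(thermograms); ns <- length(species)
  lb0 <- vapply(species, `[[`, numeric(1), "log_beta")

  weights_mask <- lapply(thermograms, function(tg) {
    w <- rep(TRUE, length(tg$heats)); if (exclude_first) w[1] <- FALSE; w
  })
  mask <- unlist(weights_mask)

  y_all <- unlist(lapply(thermograms, `[[`, "heats"))
  pen_scale <- 1e3 * sum(y_all^2) + 1
  objective <- function(p) {
    lb <- p[seq_len(ns)]
    nf <- exp(p[ns + seq_len(nd)])
    pen <- sum(pmax(0, nf - n_bounds[2])^2 +
                 pmax(0, n_bounds[1] - nf)^2)
    nf <- pmin(pmax(nf, n_bounds[1]), n_bounds[2])
    inner <- .itc_inner(lb, nf, thermograms, schedules, scheme, species, pHs)
    if (!is.finite(inner$sse)) return(1e12)
    sum((y_all - inner$fitted)[mask]^2) + pen_scale * pen
  }

  # coarse deterministic grid scan on the primary constant
  grid <- seq(-4, 4, by = 1)
  g_sse <- vapply(grid, function(d)
    objective(c(lb0 + d, rep(log(n_start), nd))), numeric(1))
  best_d <- grid[which.min(g_sse)]
  starts <- c(list(c(lb0, rep(log(n_start), nd))),   # user-seeded start
              lapply(c(0, -3, -1.5, 1.5, 3), function(off)
                c(lb0 + best_d + off, rep(log(n_start), nd))))

  best <- NULL
  for (p0 in starts) {
    opt <- stats::optim(p0, objective, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-13))
    opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-13))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value) || best$value >= 1e12)
    stop("ITC fit failed to converge; best objective ", best$value)

  lb <- best$par[seq_len(ns)]
  nf <- pmin(pmax(exp(best$par[ns + seq_len(nd)]), n_bounds[1]),
             n_bounds[2])
  inner <- .itc_inner(lb, nf, thermograms, schedules, scheme, species, pHs)
  y <- y_all
  resid <- (y - inner$fitted)[mask]
  rms <- sqrt(mean(resid^2))

  # identifiability diagnostics
  c_values <- vapply(seq_len(nd), function(d) {
    kp <- conditional_logK(scheme, lb[1], pHs[d])
    nf[d] * schedules[[d]]$cell_metal_conc * 10^kp
  }, numeric(1))
  # profile flatness: if shifting the primary constant by +/- 0.5 changes
  # the (re-linearised) misfit by < 10%, the constant is not resolved by
  # these data -- typical of c < 1 designs -- regardless of where the
  # point estimate landed
  sse_hat <- best$value
  sse_shift <- vapply(c(-0.5, 0.5), function(d)
    objective(c(lb + c(d, rep(0, ns - 1)), log(nf))), numeric(1))
  flat_profile <- sse_hat > 0 &&
    all(sse_shift - sse_hat < 0.1 * sse_hat)
  # a species is unsupported when removing it barely changes the misfit
  # (likelihood-ratio style check; a point-estimate amplitude can sit on a
  # flat compensation ridge and still be statistically null)
  underdet <- FALSE
  if (ns > 1) {
    sse_full <- sum((y - inner$fitted)[mask]^2)
    for (j in 2:ns) {
      # refit the reduced model: the remaining parameters must be free to
      # leave any compensation ridge the full model sat on
      red_obj <- function(p) {
        lbr <- p[seq_len(ns - 1)]
        nfr <- pmin(pmax(exp(p[(ns - 1) + seq_len(nd)]), n_bounds[1]),
                    n_bounds[2])
        ir <- .itc_inner(lbr, nfr, thermograms, schedules, scheme,
                         species[-j], pHs)
        if (!is.finite(ir$sse)) return(1e12)
        sum((y - ir$fitted)[mask]^2)
      }
      opt_red <- stats::optim(c(lb[-j], log(nf)), red_obj,
                              method = "Nelder-Mead",
                              control = list(maxit = 1000,
                                             reltol = 1e-12))
      if (opt_red$value - sse_full < max(0.05 * sse_full,
                                         1e-10 * sum(y^2)))
        underdet <- TRUE
    }
  }

  structure(list(log_betas = lb, delta_H = inner$delta_H, n_factors = nf,
                 q_dil = inner$q_dil, rms = rms, sse = best$value,
                 fitted = inner$fitted, observed = y,
                 low_c = any(c_values < 1) || flat_profile,
                 c_values = c_values,
                 underdetermined = underdet,
                 thermograms = thermograms, schedules = schedules,
                 scheme = scheme, species = species, pHs = pHs,
                 exclude_first = exclude_first, n_bounds = n_bounds),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("<itc_fit> ", length(x$thermograms), " dataset(s), ",
      length(x$species), " species\n", sep = "")
  for (j in seq_along(x$species))
    cat(sprintf("  %s: log beta = %.3f, dH = %.2f kJ/mol\n",
                x$species[[j]]$label, x$log_betas[j], x$delta_H[j] / 1000))
  cat(sprintf("  n = %s, q_dil = %s uJ, rms = %.3f uJ\n",
              paste(sprintf("%.3f", x$n_factors), collapse = "/"),
              paste(sprintf("%.2f", x$q_dil), collapse = "/"), x$rms))
  if (x$low_c) cat("  WARNING: c-value < 1; constants weakly identified\n")
  if (x$underdetermined)
    cat("  WARNING: a species contributes negligibly; model underdetermined\n")
  invisible(x)
}

#' Monte Carlo uncertainty intervals for an ITC fit
#'
#' Parametric bootstrap: `n_reps` synthetic replicates are drawn by adding
#' Gaussian noise with sigma equal to the fitted rms to the model-predicted
#' heats; each replicate is refit starting from the point estimate and the
#' central 68.3% of the replicate estimates forms the interval.  Deterministic
#' under a fixed seed.
#'
#' @param fit an [fit_itc()] result.
#' @param n_reps number of replicates (warning below 50).
#' @param seed integer RNG seed (recorded in the result).
#' @param level central interval mass (default 0.683).
#' @return object of class `mc_intervals`: matrix `intervals` (rows = lower,
#'   upper; columns = parameters), `draws`, `seed`.
#' @export
monte_carlo_errors <- function(fit, n_reps = 200, seed = 1, level = 0.683) {
  stopifnot(inherits(fit, "itc_fit"))
  if (n_reps < 50) warning("n_reps < 50: intervals will be unreliable")
  nd <- length(fit$thermograms); ns <- length(fit$species)
  p_hat <- c(fit$log_betas, log(fit$n_factors))
  mask <- unlist(lapply(fit$thermograms, function(tg) {
    w <- rep(TRUE, length(tg$heats)); if (fit$exclude_first) w[1] <- FALSE; w
  }))
  lens <- vapply(fit$thermograms, function(tg) length(tg$heats), 1L)
  set.seed(seed)
  draws <- matrix(NA_real_, n_reps, ns + ns + nd)
  for (r in seq_len(n_reps)) {
    y_rep <- fit$fitted + stats::rnorm(length(fit$fitted), 0, fit$rms)
    tg_rep <- fit$thermograms
    off <- 0
    for (d in seq_len(nd)) {
      tg_rep[[d]]$heats <- y_rep[off + seq_len(lens[d])]
      off <- off + lens[d]
    }
    clamp_n <- function(v) pmin(pmax(v, fit$n_bounds[1]), fit$n_bounds[2])
    obj <- function(p) {
      inner <- .itc_inner(p[seq_len(ns)],
                          clamp_n(exp(p[ns + seq_len(nd)])),
                          tg_rep, fit$schedules, fit$scheme, fit$species,
                          fit$pHs)
      if (!is.finite(inner$sse)) return(1e12)
      sum((y_rep - inner$fitted)[mask]^2)
    }
    opt <- stats::optim(p_hat, obj, method = "Nelder-Mead",
                        control = list(maxit = 1500, reltol = 1e-10))
    n_rep <- clamp_n(exp(opt$par[ns + seq_len(nd)]))
    inner <- .itc_inner(opt$par[seq_len(ns)], n_rep,
                        tg_rep, fit$schedules, fit$scheme, fit$species,
                        fit$pHs)
    draws[r, ] <- c(opt$par[seq_len(ns)], inner$delta_H, n_rep)
  }
  colnames(draws) <- c(paste0("log_beta_", seq_len(ns)),
                       paste0("delta_H_", seq_len(ns)),
                       paste0("n_", seq_len(nd)))
  a <- (1 - level) / 2
  intervals <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a),
                     names = FALSE)
  rownames(intervals) <- c("lower", "upper")
  structure(list(intervals = intervals, draws = draws, seed = seed,
                 level = level, n_reps = n_reps),
            class = "mc_intervals")
}

#' @export
print.mc_intervals <- function(x, ...) {
  cat("<mc_intervals> ", x$n_reps, " replicates, central ",
      round(100 * x$level, 1), "% (seed ", x$seed, ")\n", sep = "")
  print(round(x$intervals, 4))
  invisible(x)
}
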