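#' Gate-delay schedule for time-resolved luminescence detection
#'
#' Delays follow a linearly increasing step rule: the k-th increment is
#' `a * k` microseconds, so cumulative offsets are `a * k (k + 1) / 2`, added
#' to the initial delay.  Defaults mirror an ambient-temperature Eu(III)
#' measurement: 21 gates, a = 7 us, initial delay 12 us (suppressing
#' emission from higher excited states); cryogenic runs use a = 15.
#'
#' @param a per-step increment scale, microseconds (> 0).
#' @param n_gates number of gates (>= 1; schedules with < 5 gates cannot be
#'   fitted downstream).
#' @param initial_delay first gate delay, microseconds.
#' @param gate_width camera gate width, microseconds (metadata).
#' @return object of class `delay_schedule` with field `delays` (absolute
#'   delays, us).
#' @examples
#' build_delay_schedule(7, 21, 12)$delays   # 12, 19, 33, ..., 1482
#' @export
build_delay_schedule <- function(a = 7, n_gates = 21L, initial_delay = 12,
                                 gate_width = 300) {
  if (a <= 0) stop("increment scale a must be positive")
  stopifnot(n_gates >= 1)
  k <- seq_len(n_gates) - 1
  offsets <- a * k * (k + 1) / 2
  structure(list(a = a, n_gates = as.integer(n_gates),
                 initial_delay = initial_delay, gate_width = gate_width,
                 delays = initial_delay + offsets),
            class = "delay_schedule")
}

#' A luminescent species: emission spectrum, lifetime, brightness
#'
#' @param spectrum non-negative emission profile over the wavelength grid;
#'   normalised to unit (trapezoidal) area on construction.
#' @param wavelength wavelength grid, nm.
#' @param lifetime mono-exponential luminescence lifetime, milliseconds.
#' @param brightness relative emissive scale (default 1).
#' @param label species label.
#' @return object of class `luminescent_species`.
#' @export
luminescent_species <- function(spectrum, wavelength, lifetime,
                                brightness = 1, label = "") {
  stopifnot(length(spectrum) == length(wavelength), lifetime > 0,
            brightness > 0)
  if (any(spectrum < 0)) stop("spectrum must be non-negative")
  area <- .trapz(wavelength, spectrum)
  if (area <= 0) stop("spectrum has zero area")
  structure(list(spectrum = spectrum / area, wavelength = wavelength,
                 lifetime = lifetime, brightness = brightness, label = label),
            class = "luminescent_species")
}

#' A TRLFS titration data cube
#'
#' Intensities over (titration step x emission wavelength x gate delay), with
#' the chemical design (totals and pH per step) attached so that
#' speciation-linked decomposition is self-contained.
#'
#' @param intensities numeric array, dim = c(steps, wavelengths, delays),
#'   non-negative counts.
#' @param wavelength wavelength grid, nm.
#' @param schedule a [build_delay_schedule()].
#' @param metal_total,ligand_total per-step totals, mol/L.
#' @param pH fixed pH of the titration.
#' @param excitation excitation wavelength, nm (metadata).
#' @return object of class `trlfs_cube`.
#' @export
trlfs_cube <- function(intensities, wavelength, schedule,
                       metal_total, ligand_total, pH, excitation = 394) {
  stopifnot(inherits(schedule, "delay_schedule"),
            length(dim(intensities)) == 3)
  d <- dim(intensities)
  if (d[2] != length(wavelength) || d[3] != schedule$n_gates ||
      d[1] != length(metal_total) || d[1] != length(ligand_total))
    stop("intensity array dimensions inconsistent with axes")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(list(intensities = intensities, wavelength = wavelength,
                 schedule = schedule, metal_total = metal_total,
                 ligand_total = ligand_total, pH = pH,
                 excitation = excitation),
            class = "trlfs_cube")
}

# internal: reconstruct a trilinear tensor from factors (C: SxR, B: WxR,
# D: TxR) as the mode-1 unfolding S x (W*T)
.trilinear_unfold1 <- function(C, B, D) {
  Z <- .khatri_rao(D, B)        # (W*T) x R, wavelength fastest
  tcrossprod(C, Z)
}

# columnwise Khatri-Rao product: (rows(A)*rows(B)) x R with B's rows fastest
.khatri_rao <- function(A, B) {
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- as.vector(outer(B[, r], A[, r]))
  out
}

#' Mono-exponential lifetime from a decay trace
#'
#' Least-squares fit of `I(t) = I0 exp(-t / tau)`; initialised from the
#' log-linear regression, polished by nonlinear least squares.  Scale
#' invariant.
#'
#' @param delays gate delays, microseconds.
#' @param intensity measured intensities (>= 5 positive points required).
#' @return list with `tau` (milliseconds), `I0`, `rms`.
#' @export
lifetime_from_decay <- function(delays, intensity) {
  stopifnot(length(delays) == length(intensity))
  pos <- intensity > 0
  if (sum(pos) < 5) stop("need at least 5 positive intensity points")
  t_ms <- delays / 1000
  cf <- stats::lm.fit(cbind(1, t_ms[pos]), log(intensity[pos]))$coefficients
  if (cf[2] > -1e-8)
    stop("trace does not decay: fitted rate is non-negative")
  tau0 <- -1 / cf[2]
  obj <- function(lt) {
    d <- exp(-t_ms / exp(lt))
    a <- sum(intensity * d) / sum(d^2)
    sum((intensity - a * d)^2)
  }
  opt <- stats::optimize(obj, log(tau0) + c(-2, 2), tol = 1e-12)
  tau <- exp(opt$minimum)
  d <- exp(-t_ms / tau)
  I0 <- sum(intensity * d) / sum(d^2)
  list(tau = tau, I0 = I0, rms = sqrt(mean((intensity - I0 * d)^2)))
}

#' Hydration number of Eu(III) from its luminescence lifetime
#'
#' Horrocks relation `n(H2O) = 1.05 / tau - 0.44` (tau in milliseconds), with
#' the empirical +/- 0.5 systematic band.  OH oscillators of first-sphere
#' water quench the excited state; shorter lifetimes imply more coordinated
#' water.
#'
#' @param tau luminescence lifetime(s), milliseconds (> 0).
#' @return object of class `hydration_estimate`: `n_H2O`, `band` (0.5),
#'   `nearest_integer`, `tau`.
#' @examples
#' horrocks_hydration(0.385)  # ~2.29 -> about two water molecules
#' @export
horrocks_hydration <- function(tau) {
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("lifetime tau must be positive")
  n <- 1.05 / tau - 0.44
  structure(list(n_H2O = n, band = 0.5, nearest_integer = round(n),
                 tau = tau),
            class = "hydration_estimate")
}

#' @export
print.hydration_estimate <- function(x, ...) {
  for (i in seq_along(x$tau))
    cat(sprintf("tau = %.3f ms -> n(H2O) = %.2f +/- %.1f (~%d)\n",
                x$tau[i], x$n_H2O[i], x$band, x$nearest_integer[i]))
  invisible(x)
}

# internal: speciation concentration profiles for the linked mode.
# Column 1 = free metal, columns 2.. = complexes (species order).
.linked_profiles <- function(log_beta, cube, scheme, species) {
  sp <- species
  for (j in seq_along(log_beta)) sp[[j]]$log_beta <- log_beta[j]
  log_alpha <- log10_binding_polynomial(scheme, cube$pH)
  .solve_series_conc(cube$metal_total, cube$ligand_total, log_alpha, sp)
}

#' Constrained trilinear (PARAFAC) decomposition of a TRLFS cube
#'
#' Alternating least squares over the three modes with the physics of the
#' experiment imposed: emission spectra are non-negative with unit area, the
#' time mode is hard-parameterised as `exp(-t / tau_r)` with each lifetime
#' refit by a 1-D log-space search every sweep, and the concentration mode is
#' either free non-negative (`constraints = "free"`) or replaced by
#' mass-action speciation profiles with log beta as the fitted scalar
#' (`constraints = "speciation"`).  All magnitude lives in the concentration
#' mode; the time factor is 1 at zero delay.
#'
#' In speciation-linked mode a free-mode decomposition is run first; its
#' profiles seed log beta (via [fit_logK_from_profiles()]) before the joint
#' constrained refinement.  Species are reported in ascending lifetime order.
#'
#' @param cube a [trlfs_cube()].
#' @param n_species number of emitting species (rank).
#' @param constraints `"free"` or `"speciation"`.
#' @param scheme a [protolysis_scheme()], required for speciation linking.
#' @param species list of [complex_species()] (their `log_beta` seeds the
#'   search); required for speciation linking; `n_species` must equal
#'   `length(species) + 1` (free metal emits too).
#' @param seed integer seed controlling the deterministic initialisation
#'   jitter.
#' @param max_sweeps ALS sweep cap (default 500).
#' @param tol relative fit-change convergence threshold (default 1e-8).
#' @return object of class `parafac_result`: `species` (list of
#'   [luminescent_species()], ascending lifetime), `concentration_profiles`
#'   (steps x species), `lifetimes` (ms), `log_beta` (linked mode),
#'   `residual_fraction`, `n_sweeps`, `converged`, `degenerate` flag, `seed`.
#' @export
parafac_fit <- function(cube, n_species, constraints = c("free", "speciation"),
                        scheme = NULL, species = NULL, seed = 1,
                        max_sweeps = 500L, tol = 1e-8) {
  stopifnot(inherits(cube, "trlfs_cube"), n_species >= 1)
  constraints <- match.arg(constraints)
  X <- cube$intensities
  S <- dim(X)[1]; W <- dim(X)[2]; Tn <- dim(X)[3]
  if (constraints == "speciation") {
    if (is.null(scheme) || is.null(species))
      stop("speciation linking requires a scheme and a species list")
    if (n_species != length(species) + 1)
      stop("linked mode expects n_species == length(species) + 1 ",
           "(free metal plus each complex)")
  }
  R <- n_species
  t_ms <- cube$schedule$delays / 1000
  X1 <- matrix(X, S, W * Tn)                      # mode-1 unfolding
  X2 <- matrix(aperm(X, c(2, 1, 3)), W, S * Tn)   # mode-2 unfolding
  ssx <- sum(X^2)

  # --- deterministic initialisation -------------------------------------
  set.seed(seed %% .Machine$integer.max)
  sv <- svd(X2, nu = R, nv = 0)
  B <- abs(sv$u[, seq_len(R), drop = FALSE]) + 1e-9
  B <- sweep(B, 2, apply(B, 2, function(b) .trapz(cube$wavelength, b)), "/")
  tau_rng <- c(max(t_ms[2] - t_ms[1], min(t_ms[t_ms > 0])), 2 * max(t_ms))
  tau <- if (R == 1) sqrt(prod(tau_rng)) else
    exp(seq(log(tau_rng[1] * 2), log(tau_rng[2] / 2), length.out = R))
  tau <- tau * exp(stats::runif(R, -0.05, 0.05))  # seed-controlled jitter
  D <- exp(outer(-t_ms, 1 / tau))

  # free-mode warm start for speciation linking
  log_beta <- NULL
  if (constraints == "speciation") {
    free_fit <- parafac_fit(cube, n_species, "free", seed = seed,
                            max_sweeps = max_sweeps, tol = tol)
    lb0 <- vapply(species, `[[`, numeric(1), "log_beta")
    prof_fit <- tryCatch(
      fit_logK_from_profiles(free_fit$concentration_profiles, scheme,
                             cube$metal_total, cube$ligand_total, cube$pH,
                             species, n_mc = 0),
      error = function(e) NULL)
    log_beta <- if (!is.null(prof_fit)) prof_fit$log_beta else lb0
    # adopt the free-mode spectra/lifetimes (matched by profile correlation
    # to the speciation columns) as the starting point
    B <- free_fit$B; tau <- free_fit$lifetimes
    P0 <- .linked_profiles(log_beta, cube, scheme, species)
    perm <- .match_columns(free_fit$concentration_profiles, P0)
    B <- B[, perm, drop = FALSE]; tau <- tau[perm]
    D <- exp(outer(-t_ms, 1 / tau))
  }

  C <- matrix(0, S, R)
  bright <- rep(1, R)
  sse_prev <- Inf
  converged <- FALSE
  sweeps <- 0L

  update_C <- function() {
    Z <- .khatri_rao(D, B)
    for (s in seq_len(S)) C[s, ] <<- .nnls(Z, X1[s, ])
  }
  update_C_linked <- function() {
    P <- .linked_profiles(log_beta, cube, scheme, species)
    Z <- .khatri_rao(D, B)
    A <- matrix(0, S * W * Tn, R)
    for (r in seq_len(R)) A[, r] <- as.vector(outer(P[, r], Z[, r]))
    bright <<- .nnls(A, as.vector(X1))
    C <<- sweep(P, 2, bright, "*")
  }
  refit_log_beta <- function() {
    Z <- .khatri_rao(D, B)
    x_vec <- as.vector(X1)
    obj <- function(lb) {
      P <- tryCatch(.linked_profiles(lb, cube, scheme, species),
                    error = function(e) NULL)
      if (is.null(P)) return(Inf)
      A <- matrix(0, S * W * Tn, R)
      for (r in seq_len(R)) A[, r] <- as.vector(outer(P[, r], Z[, r]))
      b <- .nnls(A, x_vec)
      sum((x_vec - A %*% b)^2)
    }
    opt <- stats::optimize(obj, log_beta[1] + c(-0.5, 0.5), tol = 1e-6)
    log_beta[1] <<- opt$minimum
  }

  for (sweeps in seq_len(max_sweeps)) {
    # concentration mode
    if (constraints == "free") update_C() else {
      refit_log_beta()
      update_C_linked()
    }
    # spectral mode (non-negative), then renormalise area into C
    Z2 <- .khatri_rao(D, C)
    for (w in seq_len(W)) B[w, ] <- .nnls(Z2, X2[w, ])
    areas <- apply(B, 2, function(b) .trapz(cube$wavelength, b))
    areas[areas <= 0] <- 1
    B <- sweep(B, 2, areas, "/")
    if (constraints == "free") {
      C <- sweep(C, 2, areas, "*")
    } else {
      bright <- bright * areas
      C <- sweep(C, 2, areas, "*")
    }
    # time mode: per-species 1-D lifetime refit (amplitude folded into C)
    for (r in seq_len(R)) {
      Dr <- D; Dr[, r] <- 0
      Rres <- X1 - .trilinear_unfold1(C, B, Dr)   # X minus other species
      # projection g_t = sum_{s,w} Rres[s, w + (t-1)W] C[s,r] B[w,r]
      G <- matrix(Rres, S, W * Tn)
      g <- vapply(seq_len(Tn), function(tt) {
        block <- G[, (tt - 1) * W + seq_len(W), drop = FALSE]
        drop(C[, r] %*% block %*% B[, r])
      }, numeric(1))
      nb2 <- sum(C[, r]^2) * sum(B[, r]^2)
      if (nb2 <= 0) next
      neg_gain <- function(lt) {
        d <- exp(-t_ms / exp(lt))
        -(sum(g * d))^2 / sum(d^2)
      }
      opt <- stats::optimize(neg_gain, log(tau[r]) + c(-1.5, 1.5),
                             tol = 1e-10)
      tau[r] <- exp(opt$minimum)
      d <- exp(-t_ms / tau[r])
      alpha <- sum(g * d) / (nb2 * sum(d^2))
      if (alpha > 0) {
        if (constraints == "free") C[, r] <- C[, r] * alpha
        else { bright[r] <- bright[r] * alpha; C[, r] <- C[, r] * alpha }
      }
      D[, r] <- d
    }
    sse <- sum((X1 - .trilinear_unfold1(C, B, D))^2)
    # relative fit change, measured against the data norm so that nearly
    # perfect (noise-free) fits terminate cleanly
    if (is.finite(sse_prev) && abs(sse_prev - sse) <= tol * ssx) {
      converged <- TRUE; sse_prev <- sse; break
    }
    sse_prev <- sse
  }
  if (!converged && max_sweeps >= 50)
    warning("PARAFAC did not reach the fit-change tolerance in ",
            max_sweeps, " sweeps")

  # degeneracy: congruence of factor pairs
  degenerate <- FALSE
  if (R > 1) {
    for (r1 in 1:(R - 1)) for (r2 in (r1 + 1):R) {
      cong <- abs(.cosine(B[, r1], B[, r2]) * .cosine(D[, r1], D[, r2]) *
                    .cosine(C[, r1], C[, r2]))
      if (is.finite(cong) && cong > 0.98) degenerate <- TRUE
    }
  }
  if (degenerate)
    warning("correlated factors (congruence > 0.98): rank may be too high")

  # order species by ascending lifetime (ties: first-sample amplitude)
  o <- order(tau, -C[1, ])
  tau <- tau[o]; B <- B[, o, drop = FALSE]; C <- C[, o, drop = FALSE]
  D <- D[, o, drop = FALSE]
  if (!is.null(log_beta)) bright <- bright[o]

  spec_list <- lapply(seq_len(R), function(r)
    luminescent_species(B[, r], cube$wavelength, tau[r],
                        brightness = max(C[, r]),
                        label = paste0("species_", r)))
  structure(list(species = spec_list, concentration_profiles = C,
                 lifetimes = tau, B = B, D = D,
                 log_beta = if (!is.null(log_beta)) log_beta else NULL,
                 brightness = if (constraints == "speciation") bright else
                   NULL,
                 residual_fraction = sse_prev / ssx,
                 n_sweeps = sweeps, converged = converged,
                 degenerate = degenerate, constraints = constraints,
                 cube = cube, seed = seed),
            class = "parafac_result")
}

# match columns of A to columns of reference P by maximum correlation
.match_columns <- function(A, P) {
  R <- ncol(P)
  perm <- integer(R)
  avail <- seq_len(ncol(A))
  for (r in seq_len(R)) {
    cors <- vapply(avail, function(j) {
      v <- suppressWarnings(stats::cor(A[, j], P[, r]))
      if (is.finite(v)) v else -1
    }, numeric(1))
    pick <- avail[which.max(cors)]
    perm[r] <- pick
    avail <- setdiff(avail, pick)
  }
  perm
}

#' @export
print.parafac_result <- function(x, ...) {
  cat("<parafac_result> ", length(x$species), " species (",
      x$constraints, " mode), ", x$n_sweeps, " sweeps\n", sep = "")
  cat("  lifetimes (ms):", paste(sprintf("%.4f", x$lifetimes),
                                 collapse = ", "), "\n")
  if (!is.null(x$log_beta))
    cat("  log beta:", sprintf("%.3f", x$log_beta), "\n")
  cat(sprintf("  residual fraction: %.3e\n", x$residual_fraction))
  invisible(x)
}

#' Fit log beta by matching speciation fractions to PARAFAC profiles
#'
#' Given free-mode concentration profiles (column 1 = free metal, then one
#' column per complex), finds the formation constant(s) whose mass-action
#' profiles best match them in least squares, with one free scale per species
#' (profiles carry arbitrary brightness).  Uncertainty by the shared
#' parametric Monte Carlo engine.
#'
#' @param profiles matrix (titration steps x species) from a free-mode
#'   [parafac_fit()].
#' @param scheme a [protolysis_scheme()] (fixed).
#' @param metal_total,ligand_total per-step totals, mol/L.
#' @param pH fixed pH.
#' @param species list of [complex_species()]; `log_beta` seeds the search.
#'   Only the first constant is searched (1-D); additional species keep their
#'   seed values.
#' @param search_halfwidth log-units around the seed (default 6).
#' @param n_mc Monte Carlo replicates (default 200; 0 disables).
#' @param seed RNG seed for the Monte Carlo stage.
#' @return list: `log_beta`, `scales`, `rms`, `pinned` (logical: fit at a
#'   search bound), `mc_interval` (or NULL), `seed`.
#' @export
fit_logK_from_profiles <- function(profiles, scheme, metal_total,
                                   ligand_total, pH, species,
                                   search_halfwidth = 6, n_mc = 200,
                                   seed = 1) {
  if (inherits(species, "complex_species")) species <- list(species)
  profiles <- as.matrix(profiles)
  S <- nrow(profiles)
  stopifnot(length(metal_total) == S, length(ligand_total) == S,
            ncol(profiles) == length(species) + 1)
  lb0 <- species[[1]]$log_beta
  log_alpha <- log10_binding_polynomial(scheme, pH)

  model_P <- function(lb) {
    sp <- species
    sp[[1]]$log_beta <- lb
    .solve_series_conc(metal_total, ligand_total, log_alpha, sp)
  }
  fit_at <- function(lb, prof) {
    P <- model_P(lb)
    k <- vapply(seq_len(ncol(P)), function(j) {
      den <- sum(P[, j]^2)
      if (den <= 0) 0 else max(sum(prof[, j] * P[, j]) / den, 0)
    }, numeric(1))
    list(sse = sum((prof - sweep(P, 2, k, "*"))^2), scales = k, P = P)
  }
  bounds <- lb0 + c(-search_halfwidth, search_halfwidth)
  point <- function(prof) {
    opt <- stats::optimize(function(lb) fit_at(lb, prof)$sse, bounds,
                           tol = 1e-8)
    opt$minimum
  }
  lb_hat <- point(profiles)
  at <- fit_at(lb_hat, profiles)
  rms <- sqrt(at$sse / length(profiles))
  pinned <- min(lb_hat - bounds[1], bounds[2] - lb_hat) < 1e-3 *
    diff(bounds)
  if (pinned)
    warning("log beta fit pinned at a search bound: profiles carry no ",
            "usable complexation signal")

  mc <- NULL
  if (n_mc > 0) {
    fitted <- sweep(at$P, 2, at$scales, "*")
    set.seed(seed)
    draws <- matrix(NA_real_, n_mc, 1)
    for (r in seq_len(n_mc)) {
      prof_rep <- fitted + matrix(stats::rnorm(length(fitted), 0, rms),
                                  nrow(fitted))
      draws[r, 1] <- point(pmax(prof_rep, 0))
    }
    colnames(draws) <- "log_beta"
    mc <- .mc_quantiles(draws, 0.683)
  }
  list(log_beta = lb_hat, scales = at$scales, rms = rms, pinned = pinned,
       mc_interval = mc, seed = seed)
}
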