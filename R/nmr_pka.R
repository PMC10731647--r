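#' NMR chemical-shift titration series
#'
#' One probe signal followed across a pD titration: chemical shift (ppm)
#' against pD.  Points are sorted by pD on construction.
#'
#' @param signal_id probe label (e.g. aromatic or macrocycle proton).
#' @param pD numeric vector of pD values.
#' @param shift numeric vector of chemical shifts, ppm.
#' @param nucleus observed nucleus, metadata (default "1H").
#' @return object of class `nmr_titration_series`.
#' @export
nmr_titration_series <- function(signal_id, pD, shift, nucleus = "1H") {
  stopifnot(length(pD) == length(shift))
  if (any(!is.finite(pD)) || any(!is.finite(shift)))
    stop("pD and shift values must be finite")
  o <- order(pD)
  pD <- pD[o]; shift <- shift[o]
  if (any(duplicated(pD)))
    stop("duplicate pD values in series '", signal_id, "'")
  structure(list(signal_id = signal_id, pD = pD, shift = shift,
                 nucleus = nucleus),
            class = "nmr_titration_series")
}

#' Deuterium correction of a pH-meter reading to the pD scale
#'
#' A glass electrode calibrated with aqueous buffers under-reads in D2O by a
#' constant 0.4 units: pD = meter reading + 0.4.
#'
#' @param reading pH-meter reading(s).
#' @return pD value(s).
#' @export
pd_from_meter <- function(reading) {
  stopifnot(all(is.finite(reading)))
  reading + 0.4
}

#' Deuterium isotope correction of a pD-scale inflection to an aqueous pKa
#'
#' The same constant 0.4 relating pD to the meter reading is subtracted from
#' pD-scale titration inflections to obtain pKa values comparable to H2O
#' solutions.
#'
#' @param pD_inflection inflection point(s) on the pD scale.
#' @return aqueous-scale pKa value(s).
#' @export
deuterium_correct_pka <- function(pD_inflection) {
  stopifnot(all(is.finite(pD_inflection)))
  pD_inflection - 0.4
}

# internal: (bi)dose-response model
# delta(pD) = delta0 + sum_k A_k / (1 + 10^(s_k * (pD_k - pD)))
.dose_response <- function(pD, baseline, amplitudes, inflections, slopes) {
  y <- rep(baseline, length(pD))
  for (k in seq_along(amplitudes))
    y <- y + amplitudes[k] / (1 + 10^(slopes[k] * (inflections[k] - pD)))
  y
}

# internal: noise estimate from second differences (robust to smooth trend)
.series_noise <- function(shift) {
  if (length(shift) < 3) return(0)
  stats::sd(diff(shift, differences = 2)) / sqrt(6)
}

# internal: initial inflection guesses from the numerical derivative of a
# running-median-smoothed curve; deterministic.
.init_inflections <- function(pD, shift, n_transitions) {
  sm <- stats::runmed(shift, k = min(3, length(shift) - (1 - length(shift) %% 2)))
  d <- abs(diff(sm) / diff(pD))
  mid <- (pD[-1] + pD[-length(pD)]) / 2
  picks <- numeric(0)
  d_work <- d
  min_sep <- diff(range(pD)) / (2 * n_transitions + 1)
  for (k in seq_len(n_transitions)) {
    i <- which.max(d_work)
    picks <- c(picks, mid[i])
    d_work[abs(mid - mid[i]) < min_sep] <- -Inf
  }
  sort(picks)
}

#' Fit a sigmoidal (bi)dose-response curve to a shift titration
#'
#' Least-squares fit of
#' \deqn{\delta(pD) = \delta_0 + \sum_k A_k / (1 + 10^{s_k (pD_k - pD)})}
#' where the inflections `pD_k` estimate pKa values on the pD scale.  Slopes
#' default to 1 (one-proton transitions in fast exchange); set
#' `free_slopes = TRUE` to fit them.  For fixed slopes the baseline and
#' amplitudes are profiled out linearly and only the inflections are searched,
#' which makes the fit deterministic and fast.
#'
#' @param series an [nmr_titration_series()].
#' @param n_transitions 1 or 2 protonation transitions sensed by this probe.
#' @param free_slopes fit Hill slopes (default FALSE: fixed at 1).
#' @return object of class `dose_response_fit`: `inflections` (sorted
#'   ascending), `amplitudes`, `baseline`, `slopes`, `rms` (ppm), per-inflection
#'   `uncertainties` (covariance-based), `fitted`, and the input series.
#' @export
fit_dose_response <- function(series, n_transitions = 1L, free_slopes = FALSE) {
  stopifnot(inherits(series, "nmr_titration_series"),
            n_transitions %in% c(1L, 2L))
  pD <- series$pD; y <- series$shift
  n <- length(pD)
  if (n < 6 * n_transitions)
    stop("need at least ", 6 * n_transitions, " points for ", n_transitions,
         " transition(s); got ", n)
  noise <- .series_noise(y)
  if (diff(range(y)) < max(3 * noise, 1e-9))
    stop("degenerate fit: shift range ", signif(diff(range(y)), 3),
         " ppm is below 3x the noise estimate (", signif(noise, 3), " ppm)")

  K <- n_transitions
  # linear subproblem: given inflections (and slopes), solve delta0 + A_k by lm
  design <- function(infl, slopes) {
    X <- matrix(1, n, K + 1)
    for (k in 1:K) X[, k + 1] <- 1 / (1 + 10^(slopes[k] * (infl[k] - pD)))
    X
  }
  sse_of <- function(infl, slopes) {
    X <- design(infl, slopes)
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }

  infl0 <- .init_inflections(pD, y, K)
  obj <- function(p) {
    infl <- p[1:K]
    slopes <- if (free_slopes) exp(p[(K + 1):(2 * K)]) else rep(1, K)
    if (any(infl < min(pD) - 2) || any(infl > max(pD) + 2)) return(1e6)
    sse_of(infl, slopes)
  }
  p0 <- if (free_slopes) c(infl0, rep(0, K)) else infl0
  if (length(p0) == 1L) {
    o <- stats::optimize(obj, range(pD) + c(-1, 1), tol = 1e-10)
    opt <- list(par = o$minimum)
  } else {
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    # polish with a second restart from the optimum (Nelder-Mead can stall)
    opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
  }
  infl <- opt$par[1:K]
  slopes <- if (free_slopes) exp(opt$par[(K + 1):(2 * K)]) else rep(1, K)
  o <- order(infl); infl <- infl[o]; slopes <- slopes[o]
  if (any(infl < min(pD) - 1) || any(infl > max(pD) + 1))
    stop("fit did not converge: inflection outside observed pD range +/- 1")

  X <- design(infl, slopes)
  lin <- stats::lm.fit(X, y)
  fitted <- drop(X %*% lin$coefficients)
  resid <- y - fitted
  rms <- sqrt(mean(resid^2))

  # covariance-based uncertainty of the inflections via numeric Jacobian of
  # the full model wrt all parameters
  theta <- c(lin$coefficients, infl, if (free_slopes) slopes)
  model_at <- function(th) {
    b <- th[1]; A <- th[2:(K + 1)]; pk <- th[(K + 2):(2 * K + 1)]
    s <- if (free_slopes) th[(2 * K + 2):(3 * K + 1)] else slopes
    .dose_response(pD, b, A, pk, s)
  }
  J <- matrix(0, n, length(theta))
  h <- 1e-6
  for (j in seq_along(theta)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    J[, j] <- (model_at(tp) - model_at(tm)) / (2 * h)
  }
  dof <- max(n - length(theta), 1)
  s2 <- sum(resid^2) / dof
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  unc <- if (is.null(cov)) rep(NA_real_, K) else
    sqrt(pmax(diag(cov)[(K + 2):(2 * K + 1)], 0))

  structure(list(n_transitions = K, inflections = infl,
                 amplitudes = unname(lin$coefficients[-1]),
                 baseline = unname(lin$coefficients[1]),
                 slopes = slopes, rms = rms, uncertainties = unc,
                 fitted = fitted, series = series),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> '", x$series$signal_id, "': ",
      x$n_transitions, " transition(s)\n", sep = "")
  cat("  inflections (pD):",
      paste(sprintf("%.3f +/- %.3f", x$inflections, x$uncertainties),
            collapse = ", "), "\n")
  cat("  rms:", format(x$rms, digits = 3), "ppm\n")
  invisible(x)
}

#' Assemble a protolysis scheme from per-probe dose-response fits
#'
#' Applies the deuterium correction to every fitted inflection, merges
#' inflections from different probes that report the same transition
#' (within `merge_tol` pD units) by uncertainty-weighted mean, and returns the
#' sorted pKa ladder.  Reported per-step uncertainty is
#' `max(covariance sigma, min_uncertainty)` to honour the electrode-dominated
#' error floor.
#'
#' @param fits list of [fit_dose_response()] results.
#' @param merge_tol merge window in pD units (default 0.3).
#' @param min_uncertainty uncertainty floor (default 0.15, electrode error).
#' @param transition_ids optional list (parallel to `fits`) of integer vectors
#'   assigning each fitted inflection to a global transition index.  When
#'   given, inflections sharing an index farther apart than `merge_tol` raise
#'   an error; when absent, transitions are clustered by proximity.
#' @return a [protolysis_scheme()] with attributes `uncertainties` and
#'   `pD_inflections`.
#' @export
assemble_scheme <- function(fits, merge_tol = 0.3, min_uncertainty = 0.15,
                            transition_ids = NULL) {
  stopifnot(length(fits) >= 1)
  infl <- unlist(lapply(fits, `[[`, "inflections"))
  unc <- unlist(lapply(fits, function(f) {
    u <- f$uncertainties
    ifelse(is.finite(u), pmax(u, min_uncertainty), min_uncertainty)
  }))
  if (!is.null(transition_ids)) {
    ids <- unlist(transition_ids)
    stopifnot(length(ids) == length(infl))
  } else {
    # cluster sorted inflections: gap > merge_tol opens a new transition
    o <- order(infl)
    ids_sorted <- cumsum(c(1, diff(infl[o]) > merge_tol))
    ids <- integer(length(infl)); ids[o] <- ids_sorted
  }
  groups <- split(seq_along(infl), ids)
  merged <- vapply(groups, function(ix) {
    v <- infl[ix]
    if (diff(range(v)) > merge_tol)
      stop(sprintf(paste0("conflicting duplicate transition: inflections ",
                          "%s claimed identical but spread %.2f > %.2f"),
                   paste(sprintf("%.2f", v), collapse = "/"),
                   diff(range(v)), merge_tol))
    w <- 1 / unc[ix]^2
    sum(w * v) / sum(w)
  }, numeric(1))
  merged_unc <- vapply(groups, function(ix) {
    pmax(sqrt(1 / sum(1 / unc[ix]^2)), min_uncertainty)
  }, numeric(1))
  o <- order(merged)
  pKa <- deuterium_correct_pka(merged[o])
  scheme <- protolysis_scheme(pKa)
  attr(scheme, "uncertainties") <- unname(merged_unc[o])
  attr(scheme, "pD_inflections") <- unname(merged[o])
  scheme
}
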