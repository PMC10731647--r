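#' Stepwise protolysis scheme of a polyprotic ligand
#'
#' Bundles the stepwise acid-dissociation exponents (pKa values) of a ligand,
#' ordered most acidic first, into a validated object used by the speciation,
#' ITC and TRLFS fitters.
#'
#' @param pKa numeric vector of stepwise pKa values, most acidic first.  May
#'   be empty for an aprotic ligand.
#' @return an object of class `protolysis_scheme` with fields `pKa` and
#'   `n_protons`.
#' @examples
#' macropa_scheme <- protolysis_scheme(c(2.40, 3.13, 6.80, 7.73))
#' @export
protolysis_scheme <- function(pKa = numeric()) {
  pKa <- as.numeric(pKa)
  if (any(!is.finite(pKa)))
    stop("all pKa values must be finite")
  if (is.unsorted(pKa, strictly = FALSE))
    stop("stepwise pKa values must be ordered most acidic first (non-decreasing)")
  structure(list(pKa = pKa, n_protons = length(pKa)),
            class = "protolysis_scheme")
}

#' @export
print.protolysis_scheme <- function(x, ...) {
  cat("<protolysis_scheme> ", x$n_protons, " proton(s)",
      if (x$n_protons) paste0(": pKa = ", paste(format(x$pKa), collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Define a metal-ligand complex species
#'
#' @param m metal stoichiometric count (>= 1).
#' @param l ligand stoichiometric count (>= 1).
#' @param log_beta cumulative formation exponent with respect to free metal and
#'   the fully deprotonated ligand.
#' @param label species label, defaults to `"M<m>L<l>"`.
#' @return an object of class `complex_species`.
#' @examples
#' eu_ml  <- complex_species(1, 1, 13.0, "EuL")
#' eu_m2l <- complex_species(2, 1, 16.5, "Eu2L")
#' @export
complex_species <- function(m, l, log_beta, label = NULL) {
  stopifnot(length(m) == 1, length(l) == 1, length(log_beta) == 1)
  m <- as.integer(m); l <- as.integer(l)
  if (m < 1 || l < 1) stop("stoichiometric counts m and l must be >= 1")
  if (!is.finite(log_beta)) stop("log_beta must be finite")
  if (is.null(label)) label <- sprintf("M%dL%d", m, l)
  structure(list(m = m, l = l, log_beta = log_beta, label = label),
            class = "complex_species")
}

#' Conditions for an equilibrium speciation calculation
#'
#' The free proton concentration is taken as fixed at `10^-pH` (buffered or
#' pH-stat practice); no proton mass balance is solved.  Temperature and ionic
#' strength are metadata: all constants are conditional at the stated medium.
#'
#' @param metal_total,ligand_total total (analytical) concentrations, mol/L.
#' @param pH fixed pH, in (0, 14).
#' @param temperature degrees C (metadata, default 25).
#' @param ionic_strength mol/L (metadata, default 0.1 NaCl).
#' @return an object of class `equilibrium_conditions`.
#' @export
equilibrium_conditions <- function(metal_total, ligand_total, pH,
                                   temperature = 25, ionic_strength = 0.1) {
  if (metal_total < 0 || ligand_total < 0)
    stop("totals must be non-negative")
  if (!is.finite(pH) || pH <= 0 || pH >= 14)
    stop("pH must lie in (0, 14)")
  structure(list(metal_total = metal_total, ligand_total = ligand_total,
                 pH = pH, temperature = temperature,
                 ionic_strength = ionic_strength),
            class = "equilibrium_conditions")
}

#' Cumulative protonation constants from a stepwise pKa ladder
#'
#' Converts stepwise acid-dissociation exponents into cumulative protonation
#' exponents: `log beta_H,i` is the sum of the `i` most basic stepwise pKa
#' values (protonation order).
#'
#' @param scheme a [protolysis_scheme()].
#' @return numeric vector `log beta_H,i`, i = 1..n_protons (empty for an
#'   aprotic ligand).
#' @examples
#' protonation_betas(protolysis_scheme(c(2.40, 3.13, 6.80, 7.73)))
#' # 7.73 14.53 17.66 20.06
#' @export
protonation_betas <- function(scheme) {
  stopifnot(inherits(scheme, "protolysis_scheme"))
  if (scheme$n_protons == 0L) return(numeric())
  cumsum(rev(scheme$pKa))
}

#' Ligand binding polynomial (side-reaction coefficient) at fixed pH
#'
#' alpha_L(H) = 1 + sum_i beta_H,i [H+]^i with [H+] = 10^-pH.  Quantifies the
#' proton competition the metal faces for the ligand's donor groups; always
#' >= 1 and equal to 1 for an aprotic (or fully deprotonated) ligand.
#'
#' Computed in log space to avoid overflow for strongly basic ligands at low
#' pH.
#'
#' @param scheme a [protolysis_scheme()].
#' @param pH fixed pH.
#' @return alpha (dimensionless, >= 1).
#' @export
binding_polynomial <- function(scheme, pH) {
  stopifnot(is.finite(pH))
  lb <- protonation_betas(scheme)
  if (!length(lb)) return(1.0)
  i <- seq_along(lb)
  log_terms <- c(0, lb - i * pH)        # log10 of each summand incl. the 1
  mx <- max(log_terms)
  10^mx * sum(10^(log_terms - mx)) * 1  # log-sum-exp in base 10
}

#' log10 of the binding polynomial (overflow-safe)
#' @inheritParams binding_polynomial
#' @return log10 alpha_L(H)
#' @export
log10_binding_polynomial <- function(scheme, pH) {
  lb <- protonation_betas(scheme)
  if (!length(lb)) return(0.0)
  i <- seq_along(lb)
  log_terms <- c(0, lb - i * pH)
  mx <- max(log_terms)
  mx + log10(sum(10^(log_terms - mx)))
}

#' Conditional (apparent) stability constant at fixed pH
#'
#' log K' = log K - log10 alpha_L(H).  Monotonically increasing in pH: proton
#' competition wanes as the ligand deprotonates.
#'
#' @param scheme a [protolysis_scheme()].
#' @param log_K pH-independent stability constant (log10).
#' @param pH fixed pH.
#' @return conditional log K'.
#' @export
conditional_logK <- function(scheme, log_K, pH) {
  stopifnot(is.finite(log_K), is.finite(pH))
  log_K - log10_binding_polynomial(scheme, pH)
}

# internal: damped-Newton core on x = c(log10 [M], log10 [L]).
# Returns list(x, res, converged); mj/lj/lb are the species stoichiometries
# and cumulative constants.
.newton_free <- function(M_tot, L_tot, log_alpha, mj, lj, lb, x0,
                         tol = 1e-12, max_iter = 200L) {
  ln10 <- log(10)
  la <- log_alpha
  eval_bal <- function(x) {
    lc <- lb + mj * x[1] + lj * x[2]
    cj <- 10^lc
    M <- 10^x[1] + sum(mj * cj)
    L <- 10^(x[2] + la) + sum(lj * cj)
    list(M = M, L = L, cj = cj)
  }
  x <- x0
  bal <- eval_bal(x)
  r <- c((bal$M - M_tot) / M_tot, (bal$L - L_tot) / L_tot)
  iter <- 0L
  while (max(abs(r)) > tol && iter < max_iter) {
    iter <- iter + 1L
    cj <- bal$cj
    J11 <- ln10 * (10^x[1] + sum(mj * mj * cj))
    J12 <- ln10 * sum(mj * lj * cj)
    J21 <- ln10 * sum(lj * mj * cj)
    J22 <- ln10 * (10^(x[2] + la) + sum(lj * lj * cj))
    det <- J11 * J22 - J12 * J21
    if (!is.finite(det) || det == 0) break
    f1 <- bal$M - M_tot; f2 <- bal$L - L_tot
    s1 <- -(J22 * f1 - J12 * f2) / det
    s2 <- -(-J21 * f1 + J11 * f2) / det
    s1 <- min(max(s1, -2), 2); s2 <- min(max(s2, -2), 2)
    lambda <- 1; improved <- FALSE
    for (h in 1:30) {
      xn <- c(x[1] + lambda * s1, x[2] + lambda * s2)
      bn <- eval_bal(xn)
      rn <- c((bn$M - M_tot) / M_tot, (bn$L - L_tot) / L_tot)
      if (all(is.finite(rn)) && max(abs(rn)) < max(abs(r))) {
        x <- xn; bal <- bn; r <- rn; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(x = x, res = r, cj = bal$cj, converged = max(abs(r)) <= tol)
}

# internal: fast speciation along a series of totals with warm starts.
# Returns matrix: columns free_metal then one per species (molar).
.solve_series_conc <- function(M_tots, L_tots, log_alpha, species,
                               tol = 1e-12) {
  ns <- length(species)
  mj <- vapply(species, `[[`, integer(1), "m")
  lj <- vapply(species, `[[`, integer(1), "l")
  lb <- vapply(species, `[[`, numeric(1), "log_beta")
  n <- length(M_tots)
  out <- matrix(0, n, 1 + ns)
  x_prev <- NULL
  for (i in seq_len(n)) {
    M_tot <- M_tots[i]; L_tot <- L_tots[i]
    if (M_tot <= 0 || L_tot <= 0 || ns == 0L) {
      out[i, 1] <- M_tot
      next
    }
    x0 <- if (!is.null(x_prev)) x_prev else
      c(log10(M_tot), log10(L_tot) - log_alpha)
    sol <- .newton_free(M_tot, L_tot, log_alpha, mj, lj, lb, x0, tol)
    if (!sol$converged) {
      sol <- .newton_free(M_tot, L_tot, log_alpha, mj, lj, lb,
                          c(log10(M_tot), log10(L_tot) - log_alpha), tol)
    }
    if (!sol$converged) {
      x <- .speciation_bisect(M_tot, L_tot, log_alpha, species)
      sol <- .newton_free(M_tot, L_tot, log_alpha, mj, lj, lb, x, tol,
                          max_iter = 5L)
      if (max(abs(sol$res)) > 1e-8)
        stop(sprintf("speciation failed at series step %d (residual %.2e)",
                     i, max(abs(sol$res))))
    }
    x_prev <- sol$x
    out[i, ] <- c(10^sol$x[1], sol$cj)
  }
  colnames(out) <- c("free_metal",
                     vapply(species, `[[`, character(1), "label"))
  out
}

# internal: nested-bisection fallback. Solves the ligand balance for each
# trial [M] (monotone in [L]), then bisects the metal balance on log10 [M].
.speciation_bisect <- function(M_tot, L_tot, log_alpha, species, tol = 1e-14) {
  lj <- vapply(species, `[[`, integer(1), "l")
  mj <- vapply(species, `[[`, integer(1), "m")
  lb <- vapply(species, `[[`, numeric(1), "log_beta")
  L_of <- function(ll, lm)
    10^(ll + log_alpha) + sum(lj * 10^(lb + mj * lm + lj * ll))
  solve_l <- function(lm) {
    lo <- log10(L_tot) - 40; hi <- log10(L_tot) - log_alpha + 1e-12
    if (L_of(hi, lm) < L_tot) return(hi)
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (L_of(mid, lm) > L_tot) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  M_of <- function(lm) {
    ll <- solve_l(lm)
    10^lm + sum(mj * 10^(lb + mj * lm + lj * ll))
  }
  lo <- log10(M_tot) - 40; hi <- log10(M_tot)
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (M_of(mid) > M_tot) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  lm <- (lo + hi) / 2
  c(lm, solve_l(lm))
}

#' Solve mass-action speciation at fixed pH
#'
#' Simultaneously satisfies the metal and ligand mass balances
#' \deqn{M_{tot} = [M] + \sum_j m_j \beta_j [M]^{m_j} [L]^{l_j}}
#' \deqn{L_{tot} = [L]\,\alpha_L(H) + \sum_j l_j \beta_j [M]^{m_j} [L]^{l_j}}
#' with the free proton concentration fixed at `10^-pH`.  Solved by damped
#' Newton iteration in log10 free-concentration coordinates (analytic
#' Jacobian), with a nested-bisection fallback if Newton fails; concentrations
#' spanning many decades stay positive by construction.
#'
#' @param conditions an [equilibrium_conditions()].
#' @param scheme a [protolysis_scheme()].
#' @param species list of [complex_species()]; may be empty.
#' @param tol convergence tolerance on scaled residuals (default 1e-12).
#' @param max_iter Newton iteration cap (default 200).
#' @return an object of class `speciation_result`: free_metal, free_ligand,
#'   `complexes` (named molar concentrations), `mass_balance_residuals`
#'   (relative), and the inputs.
#' @export
solve_speciation <- function(conditions, scheme, species = list(),
                             tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(conditions, "equilibrium_conditions"),
            inherits(scheme, "protolysis_scheme"))
  if (inherits(species, "complex_species")) species <- list(species)
  M_tot <- conditions$metal_total
  L_tot <- conditions$ligand_total
  if (M_tot < 0 || L_tot < 0) stop("totals must be non-negative")
  log_alpha <- log10_binding_polynomial(scheme, conditions$pH)
  labels <- vapply(species, `[[`, character(1), "label")

  mk_result <- function(free_m, free_l, cj, res) {
    names(cj) <- labels
    structure(list(free_metal = free_m, free_ligand = free_l,
                   complexes = cj, mass_balance_residuals = res,
                   conditions = conditions, scheme = scheme,
                   species = species, log_alpha = log_alpha),
              class = "speciation_result")
  }

  # degenerate corners: a zero total forces every complex to zero
  if (M_tot == 0 || L_tot == 0 || length(species) == 0L) {
    free_m <- M_tot
    free_l <- if (L_tot > 0) L_tot / 10^log_alpha else 0
    cj <- rep(0, length(species))
    return(mk_result(free_m, free_l, cj, c(metal = 0, ligand = 0)))
  }

  mj <- vapply(species, `[[`, integer(1), "m")
  lj <- vapply(species, `[[`, integer(1), "l")
  lb <- vapply(species, `[[`, numeric(1), "log_beta")
  x0 <- c(log10(M_tot), log10(L_tot) - log_alpha)  # no-complexation start
  sol <- .newton_free(M_tot, L_tot, log_alpha, mj, lj, lb, x0,
                      tol = tol, max_iter = max_iter)
  if (!sol$converged) {
    x <- .speciation_bisect(M_tot, L_tot, log_alpha, species)
    sol <- .newton_free(M_tot, L_tot, log_alpha, mj, lj, lb, x,
                        tol = tol, max_iter = 5L)
    if (max(abs(sol$res)) > 1e-8)
      stop(sprintf(paste0("speciation failed to converge (Newton and ",
                          "bisection): residuals metal %.3e, ligand %.3e"),
                   sol$res[1], sol$res[2]))
  }
  r <- c(metal = sol$res[1], ligand = sol$res[2])
  mk_result(10^sol$x[1], 10^sol$x[2], sol$cj, r)
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("<speciation_result> pH", format(x$conditions$pH), "\n")
  cat("  free metal :", format(x$free_metal, digits = 6), "M\n")
  cat("  free ligand:", format(x$free_ligand, digits = 6), "M\n")
  if (length(x$complexes))
    for (nm in names(x$complexes))
      cat("  [", nm, "]:", format(x$complexes[[nm]], digits = 6), "M\n")
  invisible(x)
}

#' Speciation along a titration series
#'
#' Applies [solve_speciation()] to each step of a schedule; per-step failures
#' are re-signalled with the step index.
#'
#' @param schedule list of [equilibrium_conditions()] (one per titration step).
#' @param scheme a [protolysis_scheme()].
#' @param species list of [complex_species()].
#' @return list of `speciation_result`, one per step.
#' @export
titration_speciation <- function(schedule, scheme, species = list()) {
  stopifnot(is.list(schedule), length(schedule) >= 1)
  lapply(seq_along(schedule), function(i) {
    tryCatch(solve_speciation(schedule[[i]], scheme, species),
             error = function(e)
               stop(sprintf("titration step %d: %s", i, conditionMessage(e)),
                    call. = FALSE))
  })
}

#' Extract a species concentration matrix from a titration series
#'
#' @param results list of `speciation_result` from [titration_speciation()].
#' @return matrix, rows = titration steps, columns = free metal then each
#'   complex species.
#' @export
speciation_profiles <- function(results) {
  stopifnot(length(results) >= 1)
  labs <- names(results[[1]]$complexes)
  vals <- vapply(results, function(r) c(r$free_metal, unname(r$complexes)),
                 numeric(1 + length(labs)))
  out <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1)
  colnames(out) <- c("free_metal", labs)
  out
}
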