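# Independent oracles, implemented from first principles and deliberately
# sharing no code with the package's solvers.

# Side-reaction coefficient by direct term-by-term evaluation.
oracle_alpha <- function(pKa, pH) {
  if (!length(pKa)) return(1)
  logb <- cumsum(rev(pKa))          # cumulative protonation exponents
  H <- 10^(-pH)
  1 + sum(10^logb * H^seq_along(logb))
}

# Nested-bisection speciation oracle.  For each trial log10[M] the ligand
# balance (monotone increasing in [L]) is bisected, then the metal balance
# (monotone increasing in [M]) is bisected on the outside.  `species` is a
# data frame with columns m, l, log_beta.
oracle_speciation <- function(M_tot, L_tot, pKa, pH, species,
                              n_bits = 110) {
  alpha <- oracle_alpha(pKa, pH)
  mj <- species$m; lj <- species$l; lbj <- species$log_beta
  lig_balance <- function(ll, lm)
    10^ll * alpha + sum(lj * 10^(lbj + mj * lm + lj * ll))
  solve_ligand <- function(lm) {
    hi <- log10(L_tot / alpha)
    lo <- log10(L_tot) - 40
    if (lig_balance(hi, lm) < L_tot) return(hi)
    for (k in seq_len(n_bits)) {
      mid <- (lo + hi) / 2
      if (lig_balance(mid, lm) > L_tot) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  met_balance <- function(lm) {
    ll <- solve_ligand(lm)
    10^lm + sum(mj * 10^(lbj + mj * lm + lj * ll))
  }
  hi <- log10(M_tot); lo <- hi - 40
  for (k in seq_len(n_bits)) {
    mid <- (lo + hi) / 2
    if (met_balance(mid) > M_tot) hi <- mid else lo <- mid
  }
  lm <- (lo + hi) / 2
  ll <- solve_ligand(lm)
  list(free_metal = 10^lm, free_ligand = 10^ll,
       complexes = 10^(lbj + mj * lm + lj * ll))
}

# Incremental-mixing oracle for the perfusion-cell totals: each injection is
# split into tiny sub-volumes; every sub-volume displaces liquid at the
# current cell composition before (equivalently, while) mixing.
oracle_cell_totals <- function(V0, M0, L_syr, injection_volumes,
                               n_sub = 4000) {
  M <- M0; L <- 0
  out <- matrix(0, length(injection_volumes) + 1, 2)
  out[1, ] <- c(M, L)
  for (i in seq_along(injection_volumes)) {
    dv <- injection_volumes[i] / n_sub
    for (k in seq_len(n_sub)) {
      M <- M * (1 - dv / V0)
      L <- L * (1 - dv / V0) + L_syr * dv / V0
    }
    out[i + 1, ] <- c(M, L)
  }
  colnames(out) <- c("metal_total", "ligand_total")
  out
}

# Fine-bookkeeping ITC heat oracle: recomputes cumulative heats with each
# injection split into `n_sub` sub-injections (displaced-heat term applied
# per sub-injection), summing the measured heat over the sub-steps of each
# real injection.  Speciation itself comes from the independent
# nested-bisection oracle above.
oracle_injection_heats <- function(schedule, pKa, pH, species, delta_H,
                                   n_factor = 1, n_sub = 10) {
  V0 <- schedule$cell_volume
  sub_vols <- unlist(lapply(schedule$injection_volumes,
                            function(v) rep(v / n_sub, n_sub)))
  cum <- c(0, cumsum(sub_vols))
  denom <- 1 + cum / (2 * V0)
  M_tot <- n_factor * schedule$cell_metal_conc * (1 - cum / (2 * V0)) / denom
  L_tot <- schedule$syringe_conc * (cum / V0) / denom
  Qc <- vapply(seq_along(cum), function(i) {
    if (L_tot[i] <= 0 || M_tot[i] <= 0) return(0)
    sol <- oracle_speciation(M_tot[i], L_tot[i], pKa, pH, species)
    1e6 * V0 * sum(delta_H * sol$complexes)
  }, numeric(1))
  dq <- diff(Qc) + (sub_vols / V0) * (Qc[-1] + Qc[-length(Qc)]) / 2
  vapply(seq_along(schedule$injection_volumes), function(i)
    sum(dq[(i - 1) * n_sub + seq_len(n_sub)]), numeric(1))
}
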