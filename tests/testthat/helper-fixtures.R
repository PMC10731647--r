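# Shared fixtures built in code at test time.

macropa_pka <- c(2.40, 3.13, 6.80, 7.73)

macropa_scheme <- function() protolysis_scheme(macropa_pka)

eu_ml <- function(log_beta = 13.0) complex_species(1, 1, log_beta, "EuL")

# A reduced-size TRLFS cube for unit tests (coarser wavelength grid and a
# shorter titration than the acceptance design) to keep the suite fast.
small_cube <- function(log_beta = 12.9, snr = Inf, seed = 11,
                       lifetimes = c(0.109, 0.385)) {
  gen_trlfs_cube(macropa_scheme(), list(eu_ml(log_beta)),
                 lifetimes = lifetimes,
                 wavelength = seq(570, 720, by = 3),
                 ligand_total = seq(0, 112e-6, length.out = 10),
                 snr = snr, seed = seed)
}
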