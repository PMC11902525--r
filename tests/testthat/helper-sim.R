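# Shared synthetic fixtures for the test suite.  Everything is generated
# in code by the package's own forward simulator; no binary data files.

std_injection <- function() {
  injection_record(vin = 0.1, cin = 0.001, dndc = 0.145, n1 = 1.33)
}

# Generator constants used throughout (also the instrument_model defaults).
gen_constants <- function() {
  sec_constants(q_ri = 8.921e6, q_lals = 33.19, q_rals = 57.50)
}

# Nonzero baseline offsets and drifts, so preprocessing is actually tested.
dirty_baselines <- function() {
  list(baseline_offset = c(ri = 12, lals = 5, rals = 8, ivdp = 3, ivip = 0),
       baseline_drift = c(ri = 0.4, lals = -0.2, rals = 0.1, ivdp = 0.05,
                          ivip = 0))
}

# Monodisperse pullulan-like standard run with dirty baselines.
sim_standard <- function(m = 70768, rg = 0, seed = NULL, noise_frac = NULL,
                         sigma_band = 0.3) {
  sample <- sim_sample(data.frame(m = m, mass_fraction = 1, rg = rg),
                       mhs_k = 0.01956, mhs_a = 0.667)
  inst <- do.call(instrument_model,
                  c(list(sigma_band = sigma_band), dirty_baselines()))
  simulate_run(sample, std_injection(), inst, seed = seed,
               noise_frac = noise_frac)
}

# Preprocess a simulation over its full grid (flanks are quiet by design).
prep_full <- function(sim) {
  r <- range(sim$raw$vel)
  prepare_chromatogram(sim$raw, r[1], r[2])
}

# Agreement with a printed table cell: within one unit in the last printed
# digit (covers both rounding and truncation conventions of publications).
expect_printed <- function(computed, printed) {
  digits <- nchar(sub("^[^.]*\\.?", "", as.character(printed)))
  ulp <- 10^(-digits)
  expect_lte(abs(computed - printed), ulp)
}
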