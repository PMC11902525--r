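make_peak_chromatogram <- function(center = 8, sigma = 0.3,
                                   vmin = 4, vmax = 14, step = 0.01,
                                   slope = 0, intercept = 0) {
  vel <- seq(vmin, vmax, by = step)
  base <- intercept + slope * vel
  peak <- dnorm(vel, center, sigma)
  sec_chromatogram(vel, ri = base + peak, lals = base + 2 * peak,
                   rals = base + 1.5 * peak, ivdp = base + 0.1 * peak,
                   ivip = rep(2000, length(vel)))
}

test_that("select_region with explicit bounds restricts the grid", {
  raw <- make_peak_chromatogram()
  sel <- select_region(raw, 6, 10.8)
  expect_true(all(sel$vel >= 6 & sel$vel <= 10.8))
  expect_equal(attr(sel, "region"), range(sel$vel))
  expect_error(select_region(raw, 10, 6), "smaller")
  expect_error(select_region(raw, 100, 101), "no slices")
})

test_that("auto region selection brackets a Gaussian peak", {
  raw <- make_peak_chromatogram(center = 8, sigma = 0.3)
  sel <- select_region(raw)
  expect_lte(min(sel$vel), 8 - 3 * 0.3)
  expect_gte(max(sel$vel), 8 + 3 * 0.3)
  flat <- sec_chromatogram(seq(1, 2, 0.1), rep(5, 11), rep(5, 11),
                           rep(5, 11), rep(5, 11), rep(2000, 11))
  expect_error(select_region(flat), "flat")
})

test_that("fit_baseline recovers constants and exact lines", {
  vel <- seq(0, 10, 0.1)
  b <- fit_baseline(vel, rep(7, length(vel)), c(0, 1), c(9, 10))
  expect_equal(b$slope, 0)
  expect_equal(b$intercept, 7)
  b2 <- fit_baseline(vel, 2 * vel + 1, c(0, 1), c(9, 10))
  expect_equal(b2$slope, 2, tolerance = 1e-12)
  expect_equal(b2$intercept, 1, tolerance = 1e-12)
  expect_equal(predict(b2, 5), 11, tolerance = 1e-12)
})

test_that("fit_baseline sees through a peak confined between the windows", {
  vel <- seq(0, 10, 0.01)
  y <- -0.3 * vel + 4 + 50 * dnorm(vel, 5, 0.4)
  b <- fit_baseline(vel, y, c(0, 1), c(9, 10))
  expect_equal(b$slope, -0.3, tolerance = 1e-9)
  expect_equal(b$intercept, 4, tolerance = 1e-9)
})

test_that("fit_baseline rejects bad windows", {
  vel <- seq(0, 10, 0.1)
  expect_error(fit_baseline(vel, vel, c(0, 6), c(5, 10)), "overlap")
  expect_error(fit_baseline(vel, vel, c(0, 0.2), c(9, 10)), "5")
  expect_error(fit_baseline(vel, vel, c(-5, -4), c(9, 10)), "5")
})

test_that("baseline subtraction zeroes quiet windows and is idempotent", {
  raw <- make_peak_chromatogram(slope = 0.4, intercept = 12)
  sel <- select_region(raw, 4, 14)
  qw <- default_quiet_windows(sel$vel)
  bl <- lapply(setNames(nm = c("ri", "lals", "rals", "ivdp")), function(nm)
    fit_baseline(sel$vel, sel[[nm]], qw$left, qw$right))
  adj <- subtract_baseline(sel, bl)
  quiet <- sel$vel <= qw$left[2] | sel$vel >= qw$right[1]
  expect_lt(max(abs(adj$ad_ri[quiet])), 1e-9)
  # re-fitting a baseline on the adjusted trace finds essentially zero
  b2 <- fit_baseline(adj$vel, adj$ad_ri, qw$left, qw$right)
  expect_lt(abs(b2$slope), 1e-12)
  expect_lt(abs(b2$intercept), 1e-12)
  # peak height preserved
  expect_equal(max(adj$ad_ri), max(dnorm(sel$vel, 8, 0.3)), tolerance = 1e-9)
})

test_that("preprocessing is invariant to adding a line to every trace", {
  sim <- sim_standard()           # dirty baselines already applied
  clean_inst <- instrument_model(sigma_band = 0.3)
  sim0 <- simulate_run(sim$sample, sim$inj, clean_inst,
                       vel = sim$raw$vel)
  a_dirty <- prep_full(sim)
  a_clean <- prep_full(sim0)
  for (col in c("ad_ri", "ad_lals", "ad_rals", "eta_sp"))
    expect_equal(a_dirty[[col]], a_clean[[col]], tolerance = 1e-9)
})

test_that("specific_viscosity implements the bridge relation", {
  expect_equal(specific_viscosity(1, 4), 1)
  expect_equal(specific_viscosity(0, 200), 0)
  expect_equal(specific_viscosity(0.05, 200), 1e-3)
  expect_warning(out <- specific_viscosity(c(1, 1), c(4, -2)), "invalid")
  expect_true(is.na(out[2]))
  expect_equal(out[1], 1)
})

test_that("eta_sp from a simulated run equals the generating [eta]*c", {
  sim <- sim_standard()                       # monodisperse, noise-free
  adj <- prep_full(sim)
  eta_true <- sim$sample$components$eta[1]
  conc <- slice_concentrations(adj, sim$inj)
  on_peak <- adj$ad_ri > 0.1 * max(adj$ad_ri)
  expect_equal(adj$eta_sp[on_peak], eta_true * as.numeric(conc)[on_peak],
               tolerance = 1e-9)
})

test_that("normalize_to_unit_peak yields exact unit maxima", {
  adj <- prep_full(sim_standard())
  nt <- normalize_to_unit_peak(adj)
  expect_equal(unname(vapply(nt, max, numeric(1))), rep(1, 4))
  adj$ad_rals <- rep(0, nrow(adj))
  expect_error(normalize_to_unit_peak(adj), "all-zero")
})

test_that("estimate_noise_sd recovers the injected noise level", {
  sim <- sim_standard(seed = 5, noise_frac = 0.01)
  adj <- prep_full(sim)
  ns <- attr(adj, "noise_sd")
  clean <- attr(sim$raw, "clean")
  for (nm in c("ri", "lals", "rals", "ivdp")) {
    injected <- 0.01 * max(abs(clean[[nm]]))
    expect_lt(abs(ns[[nm]] / injected - 1), 0.25)
  }
  expect_equal(attr(adj, "ip_ref"), median(sim$raw$ivip), tolerance = 1e-6)
})

test_that("per-detector volume shifts are applied and validated", {
  sim <- sim_standard()
  shifted <- sim$raw
  # shift the LALS trace by +0.05 mL, then undo it via the shifts argument
  shifted$lals <- approx(shifted$vel + 0.05, shifted$lals,
                         xout = shifted$vel, rule = 2)$y
  adj0 <- prep_full(sim)
  r <- range(shifted$vel)
  adj1 <- prepare_chromatogram(shifted, r[1], r[2],
                               shifts = c(lals = 0.05))
  mid <- adj0$vel > r[1] + 1 & adj0$vel < r[2] - 1
  # two linear interpolations on a 0.01 mL grid limit the agreement
  expect_equal(adj1$ad_lals[mid], adj0$ad_lals[mid], tolerance = 1e-3)
  expect_error(prepare_chromatogram(shifted, r[1], r[2],
                                    shifts = c(bogus = 0.1)), "unknown")
})
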