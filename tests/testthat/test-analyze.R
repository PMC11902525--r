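test_that("weight fractions normalize and handle uniform input", {
  adj <- sec_adjusted(c(1, 2, 3), rep(4, 3), rep(1, 3), rep(1, 3),
                      rep(0.01, 3))
  expect_equal(weight_fractions(adj), rep(1 / 3, 3))
  adj$ad_ri <- c(-1, -1, -1)
  expect_error(weight_fractions(adj), "non-positive")
})

test_that("two equal-mass bands each carry half of the weight", {
  sim <- make_fixture("pul48_805", tempfile("fx"))$simulation
  adj <- prep_full(sim)
  w <- weight_fractions(adj)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  left <- adj$vel < 18.2   # between the two band centers
  expect_equal(sum(w[!left]), 0.5, tolerance = 1e-6)  # low-Vel = high-M band
})

test_that("slice concentrations: routes agree and scale correctly", {
  sim <- sim_standard()
  adj <- prep_full(sim)
  inj <- sim$inj
  ca <- slice_concentrations(adj, inj)
  expect_equal(attr(ca, "route"), "mass_balance")
  expect_equal(sum(as.numeric(ca) * diff(adj$vel)[1]), inj$cin * inj$vin,
               tolerance = 1e-9)
  cb <- slice_concentrations(adj, q_ri = 8.921e6, dndc = 0.145)
  expect_equal(attr(cb, "route"), "calibrated")
  expect_equal(as.numeric(ca), as.numeric(cb), tolerance = 1e-9)
  both <- slice_concentrations(adj, inj, q_ri = 8.921e6)
  expect_equal(attr(both, "concordance"), 1, tolerance = 1e-9)
  inj_half <- injection_record(inj$vin, inj$cin / 2, inj$dndc, inj$n1)
  expect_equal(as.numeric(slice_concentrations(adj, inj_half)),
               as.numeric(ca) / 2, tolerance = 1e-12)
  expect_error(slice_concentrations(adj), "either")
})

test_that("estimate_dndc inverts the RI calibration", {
  sim <- sim_standard()
  adj <- prep_full(sim)
  expect_equal(estimate_dndc(adj, sim$inj, 8.921e6), 0.145,
               tolerance = 1e-9)
  expect_equal(estimate_dndc(adj, sim$inj, 2 * 8.921e6), 0.145 / 2,
               tolerance = 1e-9)
  adj$ad_ri <- -adj$ad_ri
  expect_error(estimate_dndc(adj, sim$inj, 8.921e6), "non-positive")
})

test_that("slice molecular weights recover a monodisperse standard", {
  sim <- sim_standard()      # Rg = 0
  adj <- prep_full(sim)
  conc <- slice_concentrations(adj, sim$inj)
  on_peak <- adj$ad_ri > 0.02 * max(adj$ad_ri)
  m_l <- slice_mw(adj, conc, gen_constants(), 1.33, 0.145, "lals")
  m_r <- slice_mw(adj, conc, gen_constants(), 1.33, 0.145, "rals")
  expect_equal(m_l[on_peak], rep(70768, sum(on_peak)), tolerance = 1e-6)
  expect_equal(m_r[on_peak], m_l[on_peak], tolerance = 1e-6)
})

test_that("the Rg correction reconciles RALS with LALS", {
  sim <- sim_standard(rg = 30)
  adj <- prep_full(sim)
  conc <- slice_concentrations(adj, sim$inj)
  on_peak <- adj$ad_ri > 0.02 * max(adj$ad_ri)
  m_l <- slice_mw(adj, conc, gen_constants(), 1.33, 0.145, "lals")
  m_r <- slice_mw(adj, conc, gen_constants(), 1.33, 0.145, "rals")
  m_rc <- slice_mw(adj, conc, gen_constants(), 1.33, 0.145, "rals", rg = 30)
  expect_true(all(m_r[on_peak] < m_l[on_peak]))
  expect_equal(m_rc[on_peak], m_l[on_peak], tolerance = 1e-6)
})

test_that("Rg from the two-angle ratio inverts the forward model", {
  sim <- sim_standard(rg = 30)
  adj <- prep_full(sim)
  on_peak <- adj$ad_ri > 0.02 * max(adj$ad_ri)
  rg <- slice_rg_from_ratio(adj, gen_constants())
  expect_equal(rg[on_peak], rep(30, sum(on_peak)), tolerance = 1e-6)
  # a point scatterer gives Rg = 0; the Table-1 Schizophyllan ratio, 72.3 nm
  adj2 <- sec_adjusted(c(1, 2, 3), rep(1, 3), rep(1, 3) * 33.19,
                       rep(1, 3) * 57.50, rep(0.01, 3))
  expect_equal(slice_rg_from_ratio(adj2, gen_constants()), rep(0, 3))
  r <- 1 / 1.61
  adj3 <- sec_adjusted(c(1, 2, 3), rep(1, 3), rep(33.19, 3),
                       rep(57.50 * r, 3), rep(0.01, 3))
  setup <- optical_setup(lambda0 = 632.8, n = 1.33)
  expect_equal(slice_rg_from_ratio(adj3, gen_constants(), setup),
               rep(72.3, 3), tolerance = 1e-2)
  # unphysical ratios (beyond noise tolerance) are flagged NA
  adj4 <- sec_adjusted(c(1, 2, 3), rep(1, 3), rep(33.19, 3),
                       rep(57.50 * 1.5, 3), rep(0.01, 3))
  expect_true(all(is.na(slice_rg_from_ratio(adj4, gen_constants()))))
})

test_that("intrinsic viscosity estimators match their formulas", {
  expect_equal(as.numeric(slice_intrinsic_viscosity(0.5, 0.01)), 43.4822,
               tolerance = 1e-5)
  expect_equal(as.numeric(slice_intrinsic_viscosity(0.5, 0.01,
                                                    method = "ratio")), 50)
  # small-eta_sp agreement of the two estimators
  a <- slice_intrinsic_viscosity(1e-6, 1)
  b <- slice_intrinsic_viscosity(1e-6, 1, method = "ratio")
  expect_lt(abs(a / b - 1), 1e-6)
  # Solomon-Ciuta never exceeds the ratio estimator
  eta_sp <- 10^seq(-6, 1, length.out = 50)
  sc <- slice_intrinsic_viscosity(eta_sp, rep(0.01, 50))
  rt <- slice_intrinsic_viscosity(eta_sp, rep(0.01, 50), method = "ratio")
  expect_true(all(sc <= rt))
  expect_error(slice_intrinsic_viscosity(-1.5, 0.01), "unphysical")
  clipped <- slice_intrinsic_viscosity(c(-0.1, 0.5), c(0.01, 0.01))
  expect_equal(clipped[1], 0)
  expect_equal(attr(clipped, "n_clipped"), 1L)
})

test_that("number fractions and averages match the arithmetic oracle", {
  w <- c(0.5, 0.5)
  m <- c(48800, 805000)
  x <- number_fractions(w, m)
  expect_equal(x, c(0.94284, 0.05716), tolerance = 1e-4)
  expect_equal(sum(x), 1, tolerance = 1e-12)
  av <- mw_averages(w, m)
  expect_equal(av$mw, 426900, tolerance = 1e-9)
  expect_equal(av$mn, 92022, tolerance = 1e-4)
  expect_equal(av$mz, 761777, tolerance = 1e-5)
  expect_true(av$mn <= av$mw && av$mw <= av$mz)
  expect_gte(av$pdi, 1)
  # monodisperse: all averages collapse, PDI = 1
  av1 <- mw_averages(1, 70768)
  expect_equal(unlist(av1[c("mn", "mw", "mz")]), rep(70768, 3),
               ignore_attr = TRUE)
  expect_equal(av1$pdi, 1)
})

test_that("power-mean ordering holds for random weightings", {
  set.seed(42)
  for (i in 1:20) {
    w <- runif(10); w <- w / sum(w)
    m <- 10^runif(10, 3, 7)
    av <- mw_averages(w, m)
    expect_true(av$mn <= av$mw + 1e-9 && av$mw <= av$mz + 1e-9)
    expect_gte(av$pdi, 1 - 1e-12)
  }
})

test_that("bulk intrinsic viscosity is the weight-average of slices", {
  expect_equal(bulk_intrinsic_viscosity(c(0.5, 0.5), c(25.1, 170)), 97.55)
  expect_equal(bulk_intrinsic_viscosity(1, 33.6), 33.6)
})

test_that("MHS evaluation and fitting are mutually consistent", {
  expect_equal(signif(mhs_evaluate(0.01956, 0.667, 70700), 3), 33.6)
  expect_equal(signif(mhs_evaluate(0.01956, 0.667, 805000), 4), 170.0)
  m <- 10^seq(4, 6, length.out = 20)
  fit <- mhs_fit(m, mhs_evaluate(0.02, 0.7, m))
  expect_equal(fit$k, 0.02, tolerance = 1e-9)
  expect_equal(fit$a, 0.7, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_false(fit$weighted)
  expect_error(mhs_fit(c(1e5, 2e5), c(10, 12)), "at least")
  expect_error(mhs_fit(rep(1e5, 5) * (1 + 1e-9 * (1:5)),
                       rep(10, 5)), "narrow")
})

test_that("weighted MHS fit reduces to the plain fit on exact data", {
  m <- 10^seq(4, 6, length.out = 20)
  eta <- mhs_evaluate(0.02, 0.7, m)
  v0 <- rep(1e-12, 20)
  fit <- mhs_fit(m, eta, var_logm = v0, var_logeta = v0)
  expect_true(fit$weighted)
  expect_equal(fit$a, 0.7, tolerance = 1e-6)
  expect_equal(fit$k, 0.02, tolerance = 1e-4)
})

test_that("mwd_table sorts, normalizes and accumulates to 1", {
  sim <- make_fixture("pul48_805", tempfile("fx"))$simulation
  adj <- prep_full(sim)
  res <- analyze_sample(adj, gen_constants(), inj = sim$inj)
  d <- mwd_table(res$slices)
  expect_false(is.unsorted(d$m))
  expect_equal(sum(d$w), 1, tolerance = 1e-12)
  expect_equal(d$cum_w[nrow(d)], 1, tolerance = 1e-12)
  # the two modes sit at the generating molecular weights
  lo <- d[d$m < 2e5, ]; hi <- d[d$m >= 2e5, ]
  expect_equal(lo$m[which.max(lo$w)], 48800, tolerance = 0.02)
  expect_equal(hi$m[which.max(hi$w)], 805000, tolerance = 0.02)
})

test_that("export_multihydfit writes and decimates the (M, eta, Rg) table", {
  sl <- data.frame(m_lals = 10^seq(4, 6, length.out = 1000),
                   eta_intr = mhs_evaluate(0.02, 0.7,
                                           10^seq(4, 6, length.out = 1000)),
                   masked = FALSE)
  path <- tempfile()
  out <- export_multihydfit(sl, path)
  d <- attr(out, "data")
  expect_equal(nrow(d), 100L)
  expect_true(file.exists(path))
  sl3 <- sl[1:3, ]
  out3 <- export_multihydfit(sl3, path)
  expect_equal(nrow(attr(out3, "data")), 3L)
  sl_bad <- sl; sl_bad$masked <- TRUE
  expect_error(export_multihydfit(sl_bad, path), "no unmasked")
})

test_that("analyze_sample masks tails and summarizes a monodisperse run", {
  sim <- sim_standard()
  adj <- prep_full(sim)
  res <- analyze_sample(adj, gen_constants(), inj = sim$inj)
  s <- res$summary
  expect_equal(s$mw, 70768, tolerance = 1e-6)
  expect_equal(s$pdi, 1, tolerance = 1e-9)
  expect_equal(s$recovered_mass_fraction, 1, tolerance = 1e-9)
  expect_true(all(is.na(res$slices$m_lals[res$slices$masked])))
  expect_equal(sum(res$slices$x[!res$slices$masked]), 1, tolerance = 1e-9)
  expect_gt(s$n_masked, 0)
})

test_that("analyze_sample estimates dn/dc when the record lacks it", {
  sim <- sim_standard()
  adj <- prep_full(sim)
  inj_unknown <- injection_record(0.1, 0.001, n1 = 1.33)
  res <- analyze_sample(adj, gen_constants(), inj = inj_unknown)
  expect_equal(res$summary$dndc_used, 0.145, tolerance = 1e-9)
  expect_equal(res$summary$dndc_source, "estimated")
  expect_equal(res$summary$mw, 70768, tolerance = 1e-6)
})
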