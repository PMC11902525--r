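test_that("injection_record validates its fields", {
  inj <- injection_record(0.1, 0.001, 0.145, 1.33)
  expect_s3_class(inj, "sec_injection")
  expect_true(inj$dndc_known)
  expect_false(injection_record(0.1, 0.001, n1 = 1.33)$dndc_known)
  expect_error(injection_record(-1, 0.001, 0.145, 1.33))
  expect_error(injection_record(0.1, 0, 0.145, 1.33))
  expect_error(injection_record(0.1, 0.001, 0.145, 0.9))
})

test_that("read_init parses a well-formed metadata file", {
  path <- tempfile()
  writeLines(c("# comment", "Vin = 0.1", "cin = 0.001",
               "dndc = 0.145", "n1 = 1.33"), path)
  inj <- read_init(path)
  expect_equal(inj$vin, 0.1)
  expect_equal(inj$cin, 0.001)
  expect_equal(inj$dndc, 0.145)
  expect_equal(inj$n1, 1.33)
  expect_true(inj$dndc_known)
})

test_that("read_init flags unknown dn/dc and rejects missing n1", {
  path <- tempfile()
  writeLines(c("Vin = 0.1", "cin = 0.001", "dndc = unknown", "n1 = 1.33"),
             path)
  expect_false(read_init(path)$dndc_known)
  writeLines(c("Vin = 0.1", "cin = 0.001", "dndc = 0.145"), path)
  expect_error(read_init(path), "n1")
  writeLines(c("Vin = zero", "cin = 0.001", "n1 = 1.33"), path)
  expect_error(read_init(path), "malformed")
})

test_that("init file round trip preserves the record", {
  path <- tempfile()
  inj <- std_injection()
  write_init(path, inj)
  back <- read_init(path)
  expect_equal(back$vin, inj$vin)
  expect_equal(back$dndc, inj$dndc, tolerance = 1e-9)
  write_init(path, injection_record(0.1, 0.001, n1 = 1.33))
  expect_false(read_init(path)$dndc_known)
})

test_that("read_raw_signals parses a 3-row table and skips comments", {
  path <- tempfile()
  writeLines(c("# sample = demo", "1.0 10 20 30 5 2000",
               "1.1 11 21 31 6 2001", "1.2 12 22 32 7 2002"), path)
  raw <- read_raw_signals(path)
  expect_s3_class(raw, "sec_chromatogram")
  expect_equal(nrow(raw), 3L)
  expect_equal(raw$ivip, c(2000, 2001, 2002))
  expect_equal(attr(raw, "sample"), "demo")
})

test_that("read_raw_signals accepts commas and a column-order override", {
  path <- tempfile()
  writeLines(c("1.0,10,20,30,5,2000", "1.1,11,21,31,6,2001",
               "1.2,12,22,32,7,2002"), path)
  raw <- read_raw_signals(path)
  expect_equal(raw$ri, c(10, 11, 12))
  # same numbers, declared as a permuted on-disk order
  perm <- c("vel", "ivip", "ri", "lals", "rals", "ivdp")
  raw2 <- read_raw_signals(path, columns = perm)
  expect_equal(raw2$ivip, c(10, 11, 12))
  expect_equal(raw2$ri, c(20, 21, 22))
  expect_error(read_raw_signals(path, columns = c("vel", "ri")),
               "permutation")
})

test_that("raw reader rejects malformed tables with line context", {
  path <- tempfile()
  writeLines(c("1.0 10 20 30 5 2000", "1.0 11 21 31 6 2001",
               "1.2 12 22 32 7 2002"), path)
  expect_error(read_raw_signals(path), "increasing")
  writeLines(c("1.0 10 20 30 5", "1.1 11 21 31 6"), path)
  expect_error(read_raw_signals(path), "columns")
  writeLines(c("1.0 10 20 30 5 2000", "1.1 11 21 31 6"), path)
  expect_error(read_raw_signals(path), "line 2")
  writeLines(c("1.0 10 20 30 5 2000", "1.1 11 xx 31 6 2001",
               "1.2 12 22 32 7 2002"), path)
  expect_error(read_raw_signals(path), "line 2")
  writeLines("# header only, no data", path)
  expect_error(read_raw_signals(path), "no data rows")
  expect_error(read_raw_signals(tempfile()), "not found")
})

test_that("grid validation enforces length, monotonicity and uniformity", {
  expect_error(sec_chromatogram(c(1, 2), 1:2, 1:2, 1:2, 1:2, 1:2), "3")
  expect_error(sec_chromatogram(c(1, 1.1, 1.15), rep(1, 3), rep(1, 3),
                                rep(1, 3), rep(1, 3), rep(1, 3)),
               "uniform")
})

test_that("raw round trip is lossless to printed precision", {
  sim <- sim_standard()
  path <- tempfile()
  attr(sim$raw, "sample") <- "trip"
  write_raw_signals(path, sim$raw)
  back <- read_raw_signals(path)
  for (col in c("vel", "ri", "lals", "rals", "ivdp", "ivip"))
    expect_equal(back[[col]], sim$raw[[col]], tolerance = 1e-9)
  expect_equal(attr(back, "sample"), "trip")
})

test_that("adjusted round trip preserves data and noise metadata", {
  adj <- prep_full(sim_standard(seed = 11, noise_frac = 0.005))
  path <- tempfile()
  write_adjusted(path, adj)
  back <- read_adjusted(path)
  for (col in c("vel", "ad_ri", "ad_lals", "ad_rals", "eta_sp"))
    expect_equal(back[[col]], adj[[col]], tolerance = 1e-9)
  expect_equal(attr(back, "region"), attr(adj, "region"), tolerance = 1e-9)
  expect_equal(attr(back, "noise_sd"), attr(adj, "noise_sd"),
               tolerance = 1e-8)
  expect_equal(attr(back, "ip_ref"), attr(adj, "ip_ref"), tolerance = 1e-9)
})

test_that("adjusted constructor rejects degenerate input", {
  expect_error(sec_adjusted(numeric(0), numeric(0), numeric(0),
                            numeric(0), numeric(0)))
  path <- tempfile()
  writeLines("# region = 1 2", path)
  expect_error(read_adjusted(path), "no data rows")
})
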