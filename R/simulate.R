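# Forward model of the md-SEC instrument: a log-linear column places each
# component as a Gaussian elution band; the detector responses follow the
# same relations the analysis inverts; baseline offset/drift and additive
# Gaussian noise emulate the raw mV records.

#' Synthetic sample definition
#'
#' A sample is a set of discrete components, each with a molecular weight,
#' a mass fraction, an optional radius of gyration and an optional
#' per-component intrinsic viscosity.  Where no `eta` is given it is filled
#' in from the sample's Mark-Houwink-Sakurada parameters.
#'
#' @param components Data frame with columns `m` (g/mol) and
#'   `mass_fraction`, optionally `rg` (nm) and `eta` (mL/g).
#' @param mhs_k,mhs_a MHS parameters mapping M to intrinsic viscosity for
#'   components without an explicit `eta`.
#' @return An object of class `sec_sample`.
#' @export
sim_sample <- function(components, mhs_k = 0.02, mhs_a = 0.70) {
  stopifnot(is.data.frame(components),
            all(c("m", "mass_fraction") %in% names(components)))
  if (any(components$m <= 0)) stop("component molecular weights must be positive")
  if (any(components$mass_fraction < 0))
    stop("mass fractions must be non-negative")
  tot <- sum(components$mass_fraction)
  if (abs(tot - 1) > 1e-8)
    stop("component mass fractions must sum to 1")
  components$mass_fraction <- components$mass_fraction / tot
  if (is.null(components$rg)) components$rg <- 0
  components$rg[is.na(components$rg)] <- 0
  if (is.null(components$eta)) components$eta <- NA_real_
  fill <- is.na(components$eta)
  components$eta[fill] <- mhs_evaluate(mhs_k, mhs_a, components$m[fill])
  structure(list(components = components, mhs_k = mhs_k, mhs_a = mhs_a),
            class = "sec_sample")
}

#' Log-normal synthetic sample
#'
#' Discretizes a log-normal molecular weight distribution (median `median_m`,
#' geometric standard deviation `sigma_g`) into `n_components` components
#' equally spaced in log M over `median_m * sigma_g^(-z_span)` to
#' `median_m * sigma_g^(+z_span)`, with mass fractions proportional to the
#' log-normal mass density at each node.
#'
#' @param median_m Median molecular weight (g/mol).
#' @param sigma_g Geometric standard deviation (> 1).
#' @param n_components Number of discrete components.
#' @param z_span Half-width of the grid in units of `log(sigma_g)`.
#' @inheritParams sim_sample
#' @return An object of class `sec_sample`.
#' @export
sim_sample_lognormal <- function(median_m = 1e5, sigma_g = 1.8,
                                 n_components = 200L, z_span = 4,
                                 mhs_k = 0.02, mhs_a = 0.70) {
  stopifnot(sigma_g > 1, n_components >= 2L)
  z <- seq(-z_span, z_span, length.out = n_components)
  m <- median_m * sigma_g^z
  f <- stats::dnorm(z)
  sim_sample(data.frame(m = m, mass_fraction = f / sum(f)),
             mhs_k = mhs_k, mhs_a = mhs_a)
}

#' Summary statistics of a synthetic sample (generator ground truth)
#'
#' @param sample A [sim_sample()].
#' @return List with `mn`, `mw`, `mz`, `pdi`, `eta_bulk` of the discrete
#'   component set.
#' @export
sample_truth <- function(sample) {
  stopifnot(inherits(sample, "sec_sample"))
  comp <- sample$components
  av <- mw_averages(comp$mass_fraction, comp$m)
  av$eta_bulk <- sum(comp$mass_fraction * comp$eta)
  av
}

default_column <- function() {
  # Typical aqueous SEC column: exclusion at 10 mL / 5e7 g/mol, full
  # retention at 26 mL / 1e3 g/mol, log-linear in between.
  slope <- (log10(1e3) - log10(5e7)) / (26 - 10)
  column_calibration(slope = slope,
                     intercept = log10(5e7) - slope * 10,
                     vel0 = 10, velm = 26)
}

#' Instrument model for the forward simulator
#'
#' @param constants [sec_constants()] used to generate the detector
#'   responses; defaults to values typical of a triple-detector array.
#' @param setup [optical_setup()] of the LS detectors.
#' @param column [column_calibration()] mapping M to elution volume.
#' @param sigma_band Gaussian band-broadening standard deviation (mL).
#' @param ip_level Solvent-level absolute pressure of the viscometer
#'   bridge (mV); the solute contribution to IP is negligible.
#' @param baseline_offset,baseline_drift Named numeric vectors (mV and
#'   mV/mL) for detectors `ri`, `lals`, `rals`, `ivdp`, `ivip`.
#' @param noise_sd Named numeric vector of additive Gaussian noise
#'   standard deviations (mV) per detector; all zero by default so that a
#'   noise-free simulation reproduces the theory exactly.
#' @return An object of class `sec_instrument`.
#' @export
instrument_model <- function(constants = sec_constants(q_ri = 8.921e6,
                                                       q_lals = 33.19,
                                                       q_rals = 57.50),
                             setup = optical_setup(),
                             column = default_column(),
                             sigma_band = 0.3,
                             ip_level = 2000,
                             baseline_offset = c(ri = 0, lals = 0, rals = 0,
                                                 ivdp = 0, ivip = 0),
                             baseline_drift = c(ri = 0, lals = 0, rals = 0,
                                                ivdp = 0, ivip = 0),
                             noise_sd = c(ri = 0, lals = 0, rals = 0,
                                          ivdp = 0, ivip = 0)) {
  stopifnot(inherits(constants, "sec_constants"),
            inherits(setup, "optical_setup"),
            inherits(column, "column_calibration"))
  if (!is.finite(sigma_band) || sigma_band <= 0)
    stop("'sigma_band' must be positive")
  if (any(noise_sd < 0)) stop("noise standard deviations must be >= 0")
  det <- c("ri", "lals", "rals", "ivdp", "ivip")
  fill <- function(v) {
    out <- stats::setNames(numeric(5), det)
    out[names(v)] <- v
    out
  }
  structure(list(constants = constants, setup = setup, column = column,
                 sigma_band = sigma_band, ip_level = ip_level,
                 baseline_offset = fill(baseline_offset),
                 baseline_drift = fill(baseline_drift),
                 noise_sd = fill(noise_sd)),
            class = "sec_instrument")
}

#' Per-component concentration traces on an elution grid
#'
#' Each component elutes as a Gaussian band centered at the elution volume
#' the column calibration assigns to its molecular weight, scaled so that
#' the integral of its concentration over elution volume equals its
#' injected mass (`mass_fraction * cin * Vin`).  Components outside the
#' selective-permeation range are pinned at the exclusion or
#' full-retention limit with a warning.
#'
#' @param sample A [sim_sample()].
#' @param instrument An [instrument_model()].
#' @param vel Elution-volume grid (mL).
#' @param inj [injection_record()] supplying the injected mass.
#' @return Matrix (`length(vel)` x n components) of concentrations (g/mL);
#'   band centers as attribute `centers`.
#' @export
elution_profile <- function(sample, instrument, vel, inj) {
  stopifnot(inherits(sample, "sec_sample"),
            inherits(instrument, "sec_instrument"),
            inherits(inj, "sec_injection"))
  comp <- sample$components
  col <- instrument$column
  centers <- predict_elution_volume(col, comp$m)
  out_low <- centers < col$vel0
  out_high <- centers > col$velm
  if (any(out_low | out_high)) {
    warning(sum(out_low | out_high),
            " component(s) outside the selective-permeation range; ",
            "band pinned at the exclusion/full-retention limit")
    centers[out_low] <- col$vel0
    centers[out_high] <- col$velm
  }
  mass <- comp$mass_fraction * inj$cin * inj$vin
  cmat <- vapply(seq_len(nrow(comp)), function(i) {
    mass[i] * stats::dnorm(vel, centers[i], instrument$sigma_band)
  }, numeric(length(vel)))
  attr(cmat, "centers") <- centers
  cmat
}

#' Raw detector traces from per-component concentration profiles
#'
#' Generates the five raw mV traces: RI proportional to total
#' concentration; LALS proportional to the concentration-weighted molecular
#' weight; RALS additionally attenuated per component by its reciprocal
#' form factor at 90 degrees; IP at the solvent pressure level; DP from the
#' bridge relation (`DP = eta_sp * IP / 4`) with the dilute-limit
#' `eta_sp = sum_i [eta]_i c_i`.  Baseline offset/drift and additive
#' Gaussian noise are then applied per detector.
#'
#' @param cmat Concentration matrix from [elution_profile()].
#' @param sample The [sim_sample()] that generated `cmat`.
#' @param instrument An [instrument_model()].
#' @param vel Elution-volume grid (mL).
#' @param inj [injection_record()] (supplies dn/dc and n1).
#' @param noise_frac If non-`NULL`, overrides the instrument's absolute
#'   noise levels with per-detector standard deviations equal to this
#'   fraction of each detector's clean peak amplitude (of the solvent
#'   level, for IP).
#' @return A [sec_chromatogram()]; the clean (baseline- and noise-free)
#'   traces are attached as attribute `clean`.
#' @export
detector_response <- function(cmat, sample, instrument, vel, inj,
                              noise_frac = NULL) {
  stopifnot(inherits(sample, "sec_sample"),
            inherits(instrument, "sec_instrument"),
            inherits(inj, "sec_injection"))
  if (!inj$dndc_known) stop("the simulated sample's dn/dc must be known")
  comp <- sample$components
  k <- instrument$constants
  q90 <- scattering_vector(instrument$setup, 90)
  term <- angular_term(q90, comp$rg)

  c_tot <- rowSums(cmat)
  cm <- as.numeric(cmat %*% comp$m)            # sum_i c_i M_i
  cm_att <- as.numeric(cmat %*% (comp$m / term))
  eta_sp <- as.numeric(cmat %*% comp$eta)      # dilute limit: sum [eta]_i c_i

  opt <- inj$n1^2 * inj$dndc^2
  ip_clean <- rep(instrument$ip_level, length(vel))
  clean <- data.frame(
    ri = k$q_ri * inj$dndc * c_tot,
    lals = k$q_lals * opt * cm,
    rals = k$q_rals * opt * cm_att,
    ivdp = eta_sp * ip_clean / 4,
    ivip = ip_clean
  )

  sd <- instrument$noise_sd
  if (!is.null(noise_frac)) {
    stopifnot(noise_frac >= 0)
    sd <- noise_frac * vapply(clean, function(y) max(abs(y)), numeric(1))
  }
  traces <- clean
  for (nm in names(clean)) {
    traces[[nm]] <- clean[[nm]] +
      instrument$baseline_offset[[nm]] + instrument$baseline_drift[[nm]] * vel
    if (sd[[nm]] > 0)
      traces[[nm]] <- traces[[nm]] + stats::rnorm(length(vel), 0, sd[[nm]])
  }
  raw <- sec_chromatogram(vel, traces$ri, traces$lals, traces$rals,
                          traces$ivdp, traces$ivip)
  attr(raw, "clean") <- clean
  raw
}

#' Simulate a complete md-SEC run
#'
#' Convenience wrapper: builds the elution grid (if not given), the
#' per-component concentration profiles and the raw detector traces, and
#' collects the generator ground truth.
#'
#' @param sample A [sim_sample()].
#' @param inj [injection_record()] of the simulated injection.
#' @param instrument An [instrument_model()].
#' @param vel Elution-volume grid (mL); by default the component band
#'   centers padded by 12 band widths (at least 0.5 mL) with 30 grid
#'   points per band width.
#' @param seed Random seed for the noise draws (same seed, same run).
#' @param noise_frac See [detector_response()].
#' @return List of class `sec_simulation` with `raw` (the
#'   [sec_chromatogram()]), `truth` (generator parameters and the sample's
#'   true averages) and `sample`, `inj`, `instrument`.
#' @export
simulate_run <- function(sample, inj, instrument = instrument_model(),
                         vel = NULL, seed = NULL, noise_frac = NULL) {
  if (is.null(vel)) {
    centers <- predict_elution_volume(instrument$column, sample$components$m)
    centers <- pmin(pmax(centers, instrument$column$vel0), instrument$column$velm)
    pad <- max(12 * instrument$sigma_band, 0.5)
    vel <- seq(min(centers) - pad, max(centers) + pad,
               by = instrument$sigma_band / 30)
  }
  if (!is.null(seed)) set.seed(seed)
  cmat <- elution_profile(sample, instrument, vel, inj)
  raw <- detector_response(cmat, sample, instrument, vel, inj, noise_frac)
  truth <- c(sample_truth(sample),
             list(components = sample$components,
                  mhs_k = sample$mhs_k, mhs_a = sample$mhs_a,
                  constants = instrument$constants,
                  centers = attr(cmat, "centers"),
                  seed = seed, noise_frac = noise_frac))
  structure(list(raw = raw, truth = truth, sample = sample, inj = inj,
                 instrument = instrument),
            class = "sec_simulation")
}

# ---- named fixture presets --------------------------------------------------

preset_definitions <- function(preset) {
  pullulan_k <- 0.01956; pullulan_a <- 0.667
  inj <- injection_record(vin = 0.1, cin = 0.001, dndc = 0.145, n1 = 1.33)
  base <- list(
    baseline_offset = c(ri = 12, lals = 5, rals = 8, ivdp = 3, ivip = 0),
    baseline_drift = c(ri = 0.4, lals = -0.2, rals = 0.1, ivdp = 0.05,
                       ivip = 0)
  )
  switch(
    preset,
    pul71 = list(
      sample = sim_sample(data.frame(m = 70768, mass_fraction = 1),
                          mhs_k = pullulan_k, mhs_a = pullulan_a),
      inj = inj,
      instrument = do.call(instrument_model, c(list(sigma_band = 0.3), base))
    ),
    pul48_805 = list(
      sample = sim_sample(data.frame(m = c(48800, 805000),
                                     mass_fraction = c(0.5, 0.5)),
                          mhs_k = pullulan_k, mhs_a = pullulan_a),
      inj = inj,
      instrument = do.call(instrument_model, c(list(sigma_band = 0.3), base))
    ),
    polydisperse_2hec_like = list(
      sample = sim_sample_lognormal(median_m = 8e4, sigma_g = 2.4,
                                    n_components = 200L,
                                    mhs_k = 0.02, mhs_a = 0.70),
      inj = inj,
      instrument = do.call(instrument_model, c(list(sigma_band = 0.3), base))
    ),
    stop("unknown preset: ", preset)
  )
}

#' Write a named synthetic fixture to disk
#'
#' Simulates one of the built-in presets -- `"pul71"` (a practically
#' monodisperse 70.8 kDa pullulan-like standard), `"pul48_805"` (an
#' equal-mass bimodal mixture of 48.8 kDa and 805 kDa components) or
#' `"polydisperse_2hec_like"` (a broad log-normal cellulose-derivative-like
#' sample) -- and writes the injection metadata (`InitData.txt`), the raw
#' signal table (`RawSignals.txt`) and a ground-truth file
#' (`GroundTruth.txt`) holding every generator parameter.  All fixture data
#' are synthetic.
#'
#' @param preset Preset name.
#' @param dir Output directory (created if needed).
#' @param seed Random seed (the files are bit-identical for a fixed seed).
#' @param noise_frac Optional relative noise level, see
#'   [detector_response()].
#' @return Invisibly, a list with the `sec_simulation` and the three paths.
#' @export
make_fixture <- function(preset = c("pul71", "pul48_805",
                                    "polydisperse_2hec_like"),
                         dir, seed = NULL, noise_frac = NULL) {
  preset <- match.arg(preset)
  def <- preset_definitions(preset)
  sim <- simulate_run(def$sample, def$inj, def$instrument,
                      seed = seed, noise_frac = noise_frac)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(init = file.path(dir, "InitData.txt"),
                raw = file.path(dir, "RawSignals.txt"),
                truth = file.path(dir, "GroundTruth.txt"))
  write_init(paths$init, def$inj)
  attr(sim$raw, "sample") <- preset
  write_raw_signals(paths$raw, sim$raw)
  tr <- sim$truth
  meta <- list(preset = preset,
               mn = fmt_num(tr$mn), mw = fmt_num(tr$mw), mz = fmt_num(tr$mz),
               pdi = fmt_num(tr$pdi), eta_bulk = fmt_num(tr$eta_bulk),
               mhs_k = fmt_num(tr$mhs_k), mhs_a = fmt_num(tr$mhs_a),
               q_ri = fmt_num(tr$constants$q_ri),
               q_lals = fmt_num(tr$constants$q_lals),
               q_rals = fmt_num(tr$constants$q_rals),
               seed = if (is.null(seed)) "none" else as.character(seed),
               noise_frac = if (is.null(noise_frac)) "0" else
                 fmt_num(noise_frac))
  write_table_file(paths$truth, meta,
                   tr$components[c("m", "mass_fraction", "rg", "eta")])
  invisible(list(simulation = sim, paths = paths))
}
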