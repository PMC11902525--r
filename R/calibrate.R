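# Detector-constant calibration from a run of a standard of known molecular
# weight, plus classic column calibration from (Vel, M) standards.

#' Detector constants container
#'
#' Instrument constants relating detector signals (mV) to solution
#' properties under the internal units contract (c in g/mL, M in g/mol):
#' `RI = q_ri * (dn/dc) * c`, `LS = q_ls * n1^2 * (dn/dc)^2 * c * M`
#' (modulated by the reciprocal form factor for the right-angle detector).
#'
#' @param q_ri RI detector constant (mV per refractive-index unit).
#' @param q_lals,q_rals Light-scattering constants (mV per
#'   `(g/mL) * (g/mol) * (mL/g)^2` under the internal contract).
#' @param method Method tag per LS constant: `"peak"` or `"average"`.
#' @param standard Optional list of standard metadata (name, `m`, `mw`,
#'   `dndc`).
#' @return An object of class `sec_constants`.
#' @export
sec_constants <- function(q_ri, q_lals, q_rals, method = "peak",
                          standard = list()) {
  for (v in c(q_ri, q_lals, q_rals))
    if (!is.finite(v) || v <= 0) stop("detector constants must be positive")
  structure(list(q_ri = q_ri, q_lals = q_lals, q_rals = q_rals,
                 method = method, standard = standard),
            class = "sec_constants")
}

#' @export
print.sec_constants <- function(x, ...) {
  cat("md-SEC detector constants (", x$method, ")\n", sep = "")
  cat(sprintf("  Q_RI   = %.6g mV\n", x$q_ri))
  cat(sprintf("  Q_LALS = %.6g\n", x$q_lals))
  cat(sprintf("  Q_RALS = %.6g\n", x$q_rals))
  invisible(x)
}

#' RI detector constant from a standard run
#'
#' Integrates the adjusted RI trace over the selected region and divides by
#' the injected optical mass:
#' `Q_RI = sum(AdRI_j * dVel_j) / (cin * Vin * dndc_s)`.
#' Slice widths are forward differences of the elution grid (the final
#' slice reuses the previous width).
#'
#' @param adj A [sec_adjusted()] standard run.
#' @param inj The standard's [injection_record()]; its dn/dc must be known.
#' @return `Q_RI` (mV per refractive-index unit).
#' @export
ri_constant <- function(adj, inj) {
  stopifnot(inherits(adj, "sec_adjusted"), inherits(inj, "sec_injection"))
  if (!inj$dndc_known)
    stop("the standard's dn/dc must be known for RI calibration")
  integral <- sum(adj$ad_ri * delta_vel(adj$vel))
  if (!is.finite(integral) || integral <= 0)
    stop("non-positive RI integral: check the selected region and RI sign")
  integral / (inj$cin * inj$vin * inj$dndc)
}

# Mass-balance slice concentrations (the calibration route): the RI trace
# scaled so its integral equals the injected mass cin*Vin.
concentration_mass_balance <- function(adj, inj) {
  integral <- sum(adj$ad_ri * delta_vel(adj$vel))
  if (!is.finite(integral) || integral <= 0)
    stop("non-positive RI integral: check the selected region and RI sign")
  inj$cin * inj$vin * adj$ad_ri / integral
}

ls_trace <- function(adj, detector = c("lals", "rals")) {
  detector <- match.arg(detector)
  adj[[paste0("ad_", detector)]]
}

rg_factor <- function(detector, rg, setup) {
  if (is.null(rg)) return(1)
  q90 <- scattering_vector(setup, 90)
  if (detector == "rals") angular_term(q90, rg) else 1
}

#' Light-scattering detector constant from the peak slice
#'
#' For a (nearly) monodisperse standard of molecular weight `m`, the
#' signal-to-concentration ratio is constant across the peak, and the slice
#' at the LS maximum -- which maximizes the signal-to-noise ratio -- gives
#' `Q = LS_peak / (n1^2 * dndc_s^2 * c_peak * m)`.  Slice concentrations
#' come from the RI trace by mass balance.  For the right-angle detector
#' the low-angle approximation is checked when the standard's `rg` is
#' supplied; passing `rg_correct = TRUE` divides out the angular term so
#' the constant refers to a point scatterer.
#'
#' @param adj A [sec_adjusted()] standard run.
#' @param inj The standard's [injection_record()].
#' @param detector `"lals"` or `"rals"`.
#' @param m Molecular weight of the monodisperse standard (g/mol).
#' @param rg Radius of gyration of the standard (nm), if known.
#' @param rg_correct Apply the angular correction for `"rals"` (needs `rg`).
#' @param setup An [optical_setup()].
#' @return The detector constant.
#' @export
ls_constant_peak <- function(adj, inj, detector = c("lals", "rals"), m,
                             rg = NULL, rg_correct = FALSE,
                             setup = optical_setup()) {
  detector <- match.arg(detector)
  stopifnot(is.finite(m), m > 0)
  if (!inj$dndc_known) stop("the standard's dn/dc must be known")
  ls <- ls_trace(adj, detector)
  conc <- concentration_mass_balance(adj, inj)
  peak <- which.max(ls)
  if (conc[peak] <= 0) stop("non-positive concentration at the LS peak slice")
  check_la(detector, rg, setup)
  corr <- if (rg_correct) {
    if (is.null(rg)) stop("'rg_correct = TRUE' requires the standard's 'rg'")
    rg_factor(detector, rg, setup)
  } else 1
  ls[peak] * corr / (inj$n1^2 * inj$dndc^2 * conc[peak] * m)
}

check_la <- function(detector, rg, setup) {
  if (detector != "rals" || is.null(rg)) return(invisible(NULL))
  chk <- la_valid(scattering_vector(setup, 90), rg)
  if (!chk$valid)
    warning(sprintf(paste0("low-angle approximation questionable at 90 deg ",
                           "(q^2 Rg^2 / 3 = %.3g); consider rg_correct = TRUE"),
                    chk$value))
  invisible(chk)
}

#' Light-scattering detector constant from the peak-wide weight average
#'
#' Uses the whole peak rather than a single slice: the weight-averaged
#' signal-to-concentration ratio equals `Q * n1^2 * dndc_s^2 * Mw`, so
#' `Q = <LS_j / c_j>_w / (n1^2 * dndc_s^2 * Mw)`.  Only the standard's
#' weight-average molecular weight is needed.  Low-signal slices (adjusted
#' RI below `mask_threshold` of the RI peak) are excluded from the ratio
#' average, with the weight fractions renormalized over the kept slices.
#'
#' @inheritParams ls_constant_peak
#' @param mw Weight-average molecular weight of the standard (g/mol).
#' @param mask_threshold Low-signal mask threshold (fraction of RI peak).
#' @return The detector constant.
#' @export
ls_constant_average <- function(adj, inj, detector = c("lals", "rals"), mw,
                                rg = NULL, rg_correct = FALSE,
                                mask_threshold = 0.02,
                                setup = optical_setup()) {
  detector <- match.arg(detector)
  stopifnot(is.finite(mw), mw > 0)
  if (!inj$dndc_known) stop("the standard's dn/dc must be known")
  ls <- ls_trace(adj, detector)
  conc <- concentration_mass_balance(adj, inj)
  w <- weight_fractions(adj)
  keep <- adj$ad_ri >= mask_threshold * max(adj$ad_ri) & conc > 0
  if (!any(keep)) stop("no slices above the low-signal mask")
  wk <- w[keep] / sum(w[keep])
  ratio_avg <- sum(wk * ls[keep] / conc[keep])
  if (ratio_avg <= 0) stop("non-positive LS/concentration average")
  check_la(detector, rg, setup)
  corr <- if (rg_correct) {
    if (is.null(rg)) stop("'rg_correct = TRUE' requires the standard's 'rg'")
    rg_factor(detector, rg, setup)
  } else 1
  ratio_avg * corr / (inj$n1^2 * inj$dndc^2 * mw)
}

#' Full detector calibration from one standard run
#'
#' Computes `Q_RI` plus both the peak-based and average-based LS constants
#' for each light-scattering detector, and checks their mutual agreement.
#'
#' @inheritParams ls_constant_peak
#' @param mw Weight-average molecular weight (defaults to `m`).
#' @param mask_threshold Low-signal mask for the average-based constants.
#' @param spread_warn Warn if peak- and average-based constants disagree by
#'   more than this relative amount (calibration runs typically agree to a
#'   few percent).
#' @return List with elements `peak` and `average`, each a
#'   [sec_constants()] object.
#' @export
calibrate_detectors <- function(adj, inj, m, mw = m, rg = NULL,
                                rg_correct = FALSE, mask_threshold = 0.02,
                                setup = optical_setup(), spread_warn = 0.1) {
  q_ri <- ri_constant(adj, inj)
  peak <- sec_constants(
    q_ri = q_ri,
    q_lals = ls_constant_peak(adj, inj, "lals", m, rg, rg_correct, setup),
    q_rals = ls_constant_peak(adj, inj, "rals", m, rg, rg_correct, setup),
    method = "peak",
    standard = list(m = m, mw = mw, dndc = inj$dndc, rg = rg)
  )
  avg <- sec_constants(
    q_ri = q_ri,
    q_lals = ls_constant_average(adj, inj, "lals", mw, rg, rg_correct,
                                 mask_threshold, setup),
    q_rals = ls_constant_average(adj, inj, "rals", mw, rg, rg_correct,
                                 mask_threshold, setup),
    method = "average",
    standard = list(m = m, mw = mw, dndc = inj$dndc, rg = rg)
  )
  spread <- max(abs(peak$q_lals / avg$q_lals - 1),
                abs(peak$q_rals / avg$q_rals - 1))
  if (spread > spread_warn)
    warning(sprintf("peak- and average-based LS constants disagree by %.1f%%",
                    100 * spread))
  list(peak = peak, average = avg)
}

#' Write / read a detector-constants file
#'
#' Plain `key = value` text with '#' comments, holding both calibration
#' variants and the standard's metadata.
#'
#' @param path File path.
#' @param cal A list as returned by [calibrate_detectors()], or a single
#'   [sec_constants()] object.
#' @export
write_constants <- function(path, cal) {
  if (inherits(cal, "sec_constants")) cal <- stats::setNames(list(cal), cal$method)
  lines <- "# md-SEC detector constants"
  for (variant in names(cal)) {
    k <- cal[[variant]]
    lines <- c(lines,
               sprintf("%s.q_ri = %s", variant, fmt_num(k$q_ri)),
               sprintf("%s.q_lals = %s", variant, fmt_num(k$q_lals)),
               sprintf("%s.q_rals = %s", variant, fmt_num(k$q_rals)))
    std <- k$standard
    for (f in names(std))
      if (!is.null(std[[f]]) && length(std[[f]]) == 1 && is.finite(as.numeric(std[[f]])))
        lines <- c(lines, sprintf("standard.%s = %s", f, fmt_num(as.numeric(std[[f]]))))
  }
  writeLines(unique(lines), path)
  invisible(path)
}

#' @rdname write_constants
#' @return `read_constants()` returns a list of [sec_constants()] objects
#'   keyed by method.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- parse_header_meta(paste0("# ", readLines(path, warn = FALSE)))
  std_keys <- grep("^standard\\.", names(meta), value = TRUE)
  standard <- lapply(stats::setNames(meta[std_keys],
                                     sub("^standard\\.", "", std_keys)),
                     as.numeric)
  variants <- unique(sub("\\..*$", "",
                         grep("\\.q_ri$", names(meta), value = TRUE)))
  if (length(variants) == 0L) stop("no detector constants found in ", path)
  out <- lapply(stats::setNames(nm = variants), function(v) {
    sec_constants(q_ri = as.numeric(meta[[paste0(v, ".q_ri")]]),
                  q_lals = as.numeric(meta[[paste0(v, ".q_lals")]]),
                  q_rals = as.numeric(meta[[paste0(v, ".q_rals")]]),
                  method = v, standard = standard)
  })
  out
}

# ---- classic column calibration --------------------------------------------

#' Column calibration container
#'
#' The log-linear selective-permeation law of a size-exclusion column:
#' `log10(M) = intercept + slope * Vel` between the exclusion limit
#' `(Vel)0` (all larger molecules co-elute there) and the full-retention
#' limit `(Vel)m`.
#'
#' @param slope,intercept Coefficients of `log10(M)` on `Vel`; `slope < 0`.
#' @param vel0,velm Exclusion and full-retention elution volumes (mL).
#' @return An object of class `column_calibration` with derived fields
#'   `m_high` and `m_low` (the molecular weights at the two limits).
#' @export
column_calibration <- function(slope, intercept, vel0, velm) {
  if (!is.finite(slope) || slope >= 0)
    stop("calibration slope must be negative (larger M elutes earlier)")
  if (vel0 >= velm) stop("'vel0' must precede 'velm'")
  structure(list(slope = slope, intercept = intercept,
                 vel0 = vel0, velm = velm,
                 m_high = 10^(intercept + slope * vel0),
                 m_low = 10^(intercept + slope * velm)),
            class = "column_calibration")
}

#' Fit the log-linear column calibration from standards
#'
#' Least-squares fit of `log10(M)` on `Vel` through standards inside the
#' selective-permeation regime.
#'
#' @param standards Data frame with columns `vel` (mL) and `m` (g/mol);
#'   at least two rows.
#' @param vel0,velm Exclusion limits (mL); default to the fitted range.
#' @return A [column_calibration()].
#' @examples
#' cal <- fit_column_calibration(data.frame(vel = c(10, 26), m = c(5e7, 1e3)))
#' apply_column_calibration(cal, 18)  # ~2.24e5 (log-linear midpoint)
#' @export
fit_column_calibration <- function(standards, vel0 = min(standards$vel),
                                   velm = max(standards$vel)) {
  stopifnot(is.data.frame(standards), all(c("vel", "m") %in% names(standards)))
  if (nrow(standards) < 2L)
    stop("at least two standards are required for column calibration")
  fit <- stats::lm(log10(m) ~ vel, data = standards)
  column_calibration(slope = unname(stats::coef(fit)[2]),
                     intercept = unname(stats::coef(fit)[1]),
                     vel0 = vel0, velm = velm)
}

#' Apply (or invert) a column calibration
#'
#' `apply_column_calibration()` maps elution volumes to molecular weights;
#' volumes outside `[vel0, velm]` are flagged via the `"excluded"` attribute
#' (`-1` below the exclusion limit, `+1` beyond full retention, `0` inside).
#' `predict_elution_volume()` is the inverse map.
#'
#' @param cal A [column_calibration()].
#' @param vel Elution volumes (mL).
#' @return Molecular weights (g/mol).
#' @export
apply_column_calibration <- function(cal, vel) {
  stopifnot(inherits(cal, "column_calibration"))
  m <- 10^(cal$intercept + cal$slope * vel)
  flag <- integer(length(vel))
  flag[vel < cal$vel0] <- -1L
  flag[vel > cal$velm] <- 1L
  attr(m, "excluded") <- flag
  m
}

#' @rdname apply_column_calibration
#' @param m Molecular weights (g/mol).
#' @export
predict_elution_volume <- function(cal, m) {
  stopifnot(inherits(cal, "column_calibration"))
  (log10(m) - cal$intercept) / cal$slope
}

#' Universal-calibration coordinate
#'
#' The product `M * [eta]` tracks the hydrodynamic volume of the solute
#' (`Vh = M * [eta] / (nu * N_A)` with `nu = 5/2` for a sphere), so
#' `log10(M * [eta])` vs `Vel` collapses onto a single curve across polymer
#' families.
#'
#' @param m Molecular weight (g/mol).
#' @param eta Intrinsic viscosity (mL/g), positive.
#' @return `log10(m * eta)`.
#' @export
universal_coordinate <- function(m, eta) {
  if (any(!is.finite(eta)) || any(eta <= 0))
    stop("'eta' must be positive")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("'m' must be positive")
  log10(m * eta)
}
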