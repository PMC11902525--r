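# Per-slice analysis of a problem sample: concentrations, molecular weights,
# intrinsic viscosities, radii of gyration, distributions, averages, and the
# Mark-Houwink-Sakurada conformation fit.

#' Weight fraction eluting in each slice
#'
#' The mass eluting in slice j is proportional to the adjusted RI signal
#' times the slice width, so
#' `w_j = AdRI_j * dVel_j / sum(AdRI * dVel)`.  Small negative baseline
#' noise is clipped to zero before normalizing.
#'
#' @param adj A [sec_adjusted()].
#' @return Weight fractions summing to 1.
#' @export
weight_fractions <- function(adj) {
  stopifnot(inherits(adj, "sec_adjusted"))
  ri <- pmax(adj$ad_ri, 0)
  num <- ri * delta_vel(adj$vel)
  total <- sum(num)
  if (!is.finite(total) || total <= 0)
    stop("non-positive RI integral: no mass in the selected region")
  num / total
}

#' Per-slice concentrations from the RI trace
#'
#' Two routes are available and cross-checked when both are possible:
#' route A (mass balance) scales the RI trace so its integral matches the
#' injected mass, `c_j = cin * Vin * AdRI_j / sum(AdRI * dVel)`; route B
#' (calibrated) converts the signal directly,
#' `c_j = AdRI_j / (Q_RI * dndc_p)`.
#'
#' @param adj A [sec_adjusted()].
#' @param inj [injection_record()] (route A); `NULL` if unavailable.
#' @param q_ri Calibrated RI constant (route B); `NULL` if unavailable.
#' @param dndc Refractive-index increment of the problem sample (mL/g),
#'   needed by route B (defaults to the injection record's, when known).
#' @return Concentrations (g/mL) from the preferred route (A when
#'   available), with attributes `route` and -- when both routes ran --
#'   `concordance`, the ratio of the route-B to route-A integrals.
#' @export
slice_concentrations <- function(adj, inj = NULL, q_ri = NULL, dndc = NULL) {
  stopifnot(inherits(adj, "sec_adjusted"))
  if (is.null(dndc) && !is.null(inj) && inj$dndc_known) dndc <- inj$dndc
  ca <- if (!is.null(inj)) concentration_mass_balance(adj, inj)
  cb <- if (!is.null(q_ri) && !is.null(dndc)) adj$ad_ri / (q_ri * dndc)
  if (is.null(ca) && is.null(cb))
    stop("need either injection data (cin, Vin) or a calibrated Q_RI with dn/dc")
  out <- if (!is.null(ca)) ca else cb
  attr(out, "route") <- if (!is.null(ca)) "mass_balance" else "calibrated"
  if (!is.null(ca) && !is.null(cb))
    attr(out, "concordance") <- sum(cb * delta_vel(adj$vel)) /
      sum(ca * delta_vel(adj$vel))
  out
}

#' Estimate dn/dc of the problem sample from a calibrated RI detector
#'
#' When the sample's refractive-index increment is unknown but the injected
#' mass is, mass balance gives
#' `dndc_p = sum(AdRI * dVel) / (Q_RI * cin * Vin)`.
#'
#' @param adj A [sec_adjusted()].
#' @param inj [injection_record()] with known `cin`, `vin`.
#' @param q_ri Calibrated RI detector constant.
#' @return Estimated dn/dc (mL/g).
#' @export
estimate_dndc <- function(adj, inj, q_ri) {
  stopifnot(inherits(adj, "sec_adjusted"), inherits(inj, "sec_injection"))
  integral <- sum(adj$ad_ri * delta_vel(adj$vel))
  if (!is.finite(integral) || integral <= 0)
    stop("non-positive RI integral: check the selected region and RI sign")
  integral / (q_ri * inj$cin * inj$vin)
}

#' Per-slice molecular weight from a light-scattering detector
#'
#' `M_j = LS_j / (Q * n1^2 * dndc_p^2 * c_j)`.  For the right-angle
#' detector an optional radius of gyration multiplies the result by the
#' angular term `1 + q90^2 Rg^2 / 3`, undoing the form-factor attenuation.
#' Slices with non-positive concentration or signal return `NA`.
#'
#' @param adj A [sec_adjusted()].
#' @param conc Per-slice concentrations (g/mL), see [slice_concentrations()].
#' @param constants A [sec_constants()] object.
#' @param n1 Solvent refractive index.
#' @param dndc Refractive-index increment of the problem sample (mL/g).
#' @param detector `"lals"` or `"rals"`.
#' @param rg Optional radius of gyration (nm; scalar or per-slice) for the
#'   angular correction of the right-angle detector.
#' @param setup An [optical_setup()].
#' @return Molecular weights (g/mol) per slice.
#' @export
slice_mw <- function(adj, conc, constants, n1, dndc,
                     detector = c("lals", "rals"), rg = NULL,
                     setup = optical_setup()) {
  detector <- match.arg(detector)
  stopifnot(inherits(constants, "sec_constants"))
  q <- if (detector == "lals") constants$q_lals else constants$q_rals
  ls <- ls_trace(adj, detector)
  m <- ifelse(conc > 0 & ls > 0, ls / (q * n1^2 * dndc^2 * conc), NA_real_)
  if (!is.null(rg) && detector == "rals")
    m <- m * angular_term(scattering_vector(setup, 90), rg)
  m
}

#' Per-slice radius of gyration from the two-angle signal ratio
#'
#' The constant-free ratio of the two LS channels,
#' `r = (RALS_j / Q_RALS) / (LALS_j / Q_LALS)`, equals the reciprocal
#' angular term at 90 degrees, so `Rg_j = sqrt(3 * (1/r - 1)) / q90`.
#' Ratios within `[1, 1 + eps]` are treated as point scatterers (Rg = 0);
#' ratios beyond `1 + eps` are unphysical (noise) and flagged `NA`.
#'
#' @param adj A [sec_adjusted()].
#' @param constants A [sec_constants()].
#' @param setup An [optical_setup()].
#' @param eps Noise tolerance on ratios slightly above 1.
#' @return Radii of gyration (nm) per slice; `NA` where undefined.
#' @export
slice_rg_from_ratio <- function(adj, constants, setup = optical_setup(),
                                eps = 0.02) {
  stopifnot(inherits(constants, "sec_constants"))
  q90 <- scattering_vector(setup, 90)
  r <- (adj$ad_rals / constants$q_rals) / (adj$ad_lals / constants$q_lals)
  rg <- rep(NA_real_, length(r))
  ok <- is.finite(r) & r > 0 & r < 1
  rg[ok] <- sqrt(3 * (1 / r[ok] - 1)) / q90
  rg[is.finite(r) & r >= 1 & r <= 1 + eps] <- 0
  rg
}

#' Per-slice intrinsic viscosity
#'
#' At SEC dilutions the eluting slice is close to the infinite-dilution
#' limit, so the ratio estimator `[eta]_j = eta_sp_j / c_j` applies.  The
#' Solomon-Ciuta single-point estimator
#' `[eta]_j = sqrt(2 * (eta_sp - log(1 + eta_sp))) / c_j`
#' remains accurate at moderate dilution and is the default.  Negative
#' specific viscosities (baseline noise) yield 0 with a count attribute;
#' `eta_sp <= -1` is physically impossible and raises an error.
#'
#' @param eta_sp Specific viscosity per slice (dimensionless).
#' @param conc Concentration per slice (g/mL), positive where evaluated.
#' @param method `"solomon_ciuta"` (default) or `"ratio"`.
#' @return Intrinsic viscosities (mL/g); attribute `n_clipped` counts
#'   negative-`eta_sp` slices clipped to zero.
#' @examples
#' slice_intrinsic_viscosity(0.5, 0.01)                    # 43.48 mL/g
#' slice_intrinsic_viscosity(0.5, 0.01, method = "ratio")  # 50 mL/g
#' @export
slice_intrinsic_viscosity <- function(eta_sp, conc,
                                      method = c("solomon_ciuta", "ratio")) {
  method <- match.arg(method)
  if (any(eta_sp <= -1, na.rm = TRUE))
    stop("specific viscosity <= -1 is unphysical (viscosity cannot be negative)")
  clipped <- !is.na(eta_sp) & eta_sp < 0
  x <- pmax(eta_sp, 0)
  num <- switch(method,
                ratio = x,
                solomon_ciuta = sqrt(2 * (x - log1p(x))))
  out <- ifelse(!is.na(x) & conc > 0, num / conc, NA_real_)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Number fractions from weight fractions
#'
#' `x_j = (w_j / M_j) / sum(w_j / M_j)`.
#'
#' @param w Weight fractions.
#' @param m Molecular weights (g/mol).
#' @return Number fractions summing to 1.
#' @export
number_fractions <- function(w, m) {
  stopifnot(length(w) == length(m))
  num <- w / m
  num / sum(num)
}

#' Molecular weight averages and polydispersity
#'
#' `Mw = sum(w * M)`, `Mn = sum(x * M)`,
#' `Mz = sum(x * M^3) / sum(x * M^2)`, `PDI = Mw / Mn`.  The power-mean
#' inequality guarantees `Mn <= Mw <= Mz` for any weights.
#'
#' @param w Weight fractions (normalized).
#' @param m Molecular weights (g/mol).
#' @param x Number fractions; computed from `w` and `m` if omitted.
#' @return List with `mn`, `mw`, `mz` (g/mol) and `pdi`.
#' @export
mw_averages <- function(w, m, x = number_fractions(w, m)) {
  ok <- is.finite(w) & is.finite(m) & is.finite(x)
  if (!any(ok)) stop("no analyzable slices for molecular weight averages")
  w <- w[ok] / sum(w[ok]); m <- m[ok]; x <- x[ok] / sum(x[ok])
  mw <- sum(w * m)
  mn <- sum(x * m)
  mz <- sum(x * m^3) / sum(x * m^2)
  list(mn = mn, mw = mw, mz = mz, pdi = mw / mn)
}

#' Bulk intrinsic viscosity of the unfractionated sample
#'
#' Viscosity increments of the components are additive and proportional to
#' their concentrations, so `[eta]_bulk = sum(w_j * [eta]_j)`.
#'
#' @param w Weight fractions.
#' @param eta Intrinsic viscosities per slice (mL/g).
#' @return Bulk intrinsic viscosity (mL/g).
#' @export
bulk_intrinsic_viscosity <- function(w, eta) {
  ok <- is.finite(w) & is.finite(eta)
  if (!any(ok)) stop("no analyzable slices for bulk intrinsic viscosity")
  sum(w[ok] * eta[ok]) / sum(w[ok])
}

#' Mark-Houwink-Sakurada relation
#'
#' `mhs_evaluate()` computes `[eta] = K * M^a`.  `mhs_fit()` estimates
#' `(K, a)` by least squares of `log10([eta])` on `log10(M)` over slices
#' with positive `M` and `[eta]` spanning at least `min_span` decades.
#'
#' Per-slice `M` and `[eta]` are both ratios of noisy detector signals, so
#' an unweighted fit suffers from two biases: low-signal slices with huge
#' log-scale scatter dominate the residual sum, and noise in `log10(M)`
#' (the regressor) attenuates the slope toward zero -- the classical
#' errors-in-variables dilution, which the long extrapolation to `M = 1`
#' amplifies into a large error on `K`.  When per-slice measurement
#' variances are supplied, `mhs_fit()` therefore (i) weights slices by the
#' inverse total log-scale variance `1 / (var_logm + var_logeta)` and (ii)
#' applies the method-of-moments attenuation correction
#' `a = (Sxy - sum(W * cov_log)) / (Sxx - sum(W * var_logm))`, where
#' `cov_log` is the covariance of the two log coordinates induced by the
#' shared RI denominator of both ratios.
#'
#' @param k Pre-exponential coefficient (mL/g).
#' @param a Exponent (conformation indicator: ~0.5-0.8 for flexible coils
#'   in good solvents, higher for stiff chains).
#' @param m Molecular weight(s) (g/mol).
#' @return `mhs_evaluate()`: intrinsic viscosity (mL/g).
#' @examples
#' mhs_evaluate(0.01956, 0.667, 210000)  # ~69.4 mL/g (pullulan in water)
#' @export
mhs_evaluate <- function(k, a, m) {
  stopifnot(k > 0, all(m > 0))
  k * m^a
}

#' @rdname mhs_evaluate
#' @param eta Intrinsic viscosities (mL/g) paired with `m`.
#' @param min_points,min_span Minimum usable slices and minimum decades of
#'   `M` spanned.
#' @param var_logm,var_logeta Optional per-slice measurement variances of
#'   `log10(M)` and `log10([eta])` (delta-method propagation of the
#'   detector noise).  When given, the fit is inverse-variance weighted
#'   and attenuation-corrected.
#' @param cov_log Optional per-slice measurement covariance of the two log
#'   coordinates (from their shared RI denominator); defaults to 0.
#' @return `mhs_fit()`: object of class `mhs_fit` with fields `k`, `a`,
#'   `r2`, `m_range`, `n` and `weighted`.
#' @export
mhs_fit <- function(m, eta, min_points = 3L, min_span = 0.3,
                    var_logm = NULL, var_logeta = NULL, cov_log = NULL) {
  weighted <- !is.null(var_logm) && !is.null(var_logeta)
  ok <- is.finite(m) & is.finite(eta) & m > 0 & eta > 0
  if (weighted) {
    stopifnot(length(var_logm) == length(m),
              length(var_logeta) == length(m))
    if (is.null(cov_log)) cov_log <- rep(0, length(m))
    ok <- ok & is.finite(var_logm) & is.finite(var_logeta) &
      is.finite(cov_log) & var_logm >= 0 & var_logeta >= 0
  }
  if (sum(ok) < min_points)
    stop("MHS fit needs at least ", min_points, " usable slices")
  lm_ <- log10(m[ok]); le <- log10(eta[ok])
  span <- diff(range(lm_))
  if (span < min_span)
    stop(sprintf("MHS fit span of M too narrow: %.3f decades (< %.2f)",
                 span, min_span))
  if (weighted) {
    vx <- var_logm[ok]; vy <- var_logeta[ok]; cxy <- cov_log[ok]
    W <- 1 / (vx + vy)
    W <- W / sum(W)
    xb <- sum(W * lm_); yb <- sum(W * le)
    sxx <- sum(W * (lm_ - xb)^2)
    sxy <- sum(W * (lm_ - xb) * (le - yb))
    denom <- sxx - sum(W * vx)
    if (!is.finite(denom) || denom <= 0)
      stop("MHS fit: measurement variance of log10(M) exceeds its spread")
    a <- (sxy - sum(W * cxy)) / denom
    k <- 10^(yb - a * xb)
    syy <- sum(W * (le - yb)^2)
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
  } else {
    fit <- stats::lm(le ~ lm_)
    a <- unname(stats::coef(fit)[2])
    k <- 10^unname(stats::coef(fit)[1])
    ss_tot <- sum((le - mean(le))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  }
  structure(list(k = k, a = a, r2 = r2,
                 m_range = range(m[ok]), n = sum(ok),
                 weighted = weighted),
            class = "mhs_fit")
}

#' @export
print.mhs_fit <- function(x, ...) {
  cat(sprintf("MHS fit%s: [eta] = %.4g * M^%.4g (mL/g); R^2 = %.4f; n = %d\n",
              if (isTRUE(x$weighted)) " (noise-weighted)" else "",
              x$k, x$a, x$r2, x$n))
  cat(sprintf("  over M = %.3g - %.3g g/mol\n", x$m_range[1], x$m_range[2]))
  invisible(x)
}

#' Molecular weight distribution table
#'
#' Tabulates the weight-fraction distribution over molecular weight from
#' the per-slice results: `(M, w, cumulative w)` sorted by `M`, with `w`
#' renormalized over the tabulated (unmasked) slices.
#'
#' @param slices A `sec_slices` table from [analyze_sample()], or any data
#'   frame with columns `w` and the chosen M column.
#' @param detector Which molecular weight series to use.
#' @return Data frame with columns `m`, `w`, `cum_w` (cumulative, ending
#'   at 1).
#' @export
mwd_table <- function(slices, detector = c("lals", "rals")) {
  detector <- match.arg(detector)
  mcol <- paste0("m_", detector)
  ok <- is.finite(slices[[mcol]]) & is.finite(slices$w) & slices$w > 0
  if (!any(ok)) stop("no usable slices for the molecular weight distribution")
  d <- data.frame(m = slices[[mcol]][ok], w = slices$w[ok])
  d <- d[order(d$m), , drop = FALSE]
  d$w <- d$w / sum(d$w)
  d$cum_w <- cumsum(d$w)
  rownames(d) <- NULL
  d
}

#' Export per-slice (M, [eta], Rg) series for structural fitting
#'
#' Writes a plain table of molecular weight, intrinsic viscosity and (when
#' available) radius of gyration for the unmasked slices, decimated to at
#' most `max_rows` evenly spaced rows -- the input expected by external
#' global-fitting software for conformation models such as the worm-like
#' chain.
#'
#' @param slices A `sec_slices` table from [analyze_sample()].
#' @param path Output path.
#' @param max_rows Decimation cap on the number of exported rows.
#' @param detector Which molecular weight series to export.
#' @return The path, invisibly; the exported data frame as attribute.
#' @export
export_multihydfit <- function(slices, path, max_rows = 100L,
                               detector = c("lals", "rals")) {
  detector <- match.arg(detector)
  mcol <- paste0("m_", detector)
  ok <- !slices$masked & is.finite(slices[[mcol]]) &
    is.finite(slices$eta_intr) & slices[[mcol]] > 0 & slices$eta_intr > 0
  if (!any(ok)) stop("no unmasked slices to export")
  d <- data.frame(m = slices[[mcol]][ok], eta = slices$eta_intr[ok])
  has_rg <- "rg" %in% names(slices) && any(is.finite(slices$rg[ok]))
  if (has_rg) d$rg <- slices$rg[ok]
  if (nrow(d) > max_rows) {
    idx <- unique(round(seq(1L, nrow(d), length.out = max_rows)))
    d <- d[idx, , drop = FALSE]
  }
  write_table_file(path, list(columns_note = paste(names(d), collapse = " ")), d)
  out <- invisible(path)
  attr(out, "data") <- d
  out
}

#' Full slice-by-slice analysis of a problem sample
#'
#' Combines the preprocessed chromatogram with calibrated detector
#' constants to produce the per-slice table (concentration, weight and
#' number fractions, molecular weight from both LS detectors, intrinsic
#' viscosity, optional radius of gyration) and the whole-sample summary
#' (Mn, Mw, Mz, PDI, bulk intrinsic viscosity, recovered mass fraction).
#'
#' Slices whose adjusted RI falls below `mask_threshold` of the RI peak are
#' dominated by detector noise; they are excluded ("masked") from all
#' ratio-derived quantities and from the averages (whose weights are then
#' renormalized -- a deliberate truncation estimator, with the discarded
#' mass fraction reported), but retained in the integrals.  Set
#' `mask_threshold = 0` to disable masking, e.g. for noise-free synthetic
#' data; slices with non-positive RI are always masked.
#'
#' @param adj A [sec_adjusted()] problem run.
#' @param constants A [sec_constants()] object (or the `peak`/`average`
#'   list from [calibrate_detectors()], in which case `peak` is used).
#' @param inj [injection_record()] of the problem run, if available.
#' @param dndc Refractive-index increment of the problem sample; taken
#'   from `inj` when known there, else estimated via [estimate_dndc()].
#' @param n1 Solvent refractive index (defaults to `inj$n1`).
#' @param mask_threshold Low-signal mask (fraction of the RI peak).
#' @param visc_method Intrinsic-viscosity estimator, see
#'   [slice_intrinsic_viscosity()].
#' @param detector Molecular weight series used for distributions and
#'   averages; the other detector is reported alongside for concordance.
#' @param with_rg Also estimate per-slice radii of gyration from the
#'   two-angle ratio.
#' @param setup An [optical_setup()].
#' @return List of class `sec_analysis` with elements `slices` (a
#'   `sec_slices` data frame), `summary` (a `sec_summary` list) and `mhs`
#'   (an `mhs_fit`, or `NULL` if the M span is degenerate).
#' @export
analyze_sample <- function(adj, constants, inj = NULL, dndc = NULL,
                           n1 = NULL, mask_threshold = 0.02,
                           visc_method = c("solomon_ciuta", "ratio"),
                           detector = c("lals", "rals"), with_rg = FALSE,
                           setup = optical_setup()) {
  visc_method <- match.arg(visc_method)
  detector <- match.arg(detector)
  if (!inherits(constants, "sec_constants")) {
    if (is.list(constants) && !is.null(constants$peak)) constants <- constants$peak
    else stop("'constants' must be a sec_constants object")
  }
  if (is.null(n1)) {
    if (is.null(inj)) stop("supply 'n1' (or an injection record carrying it)")
    n1 <- inj$n1
  }
  conc <- slice_concentrations(adj, inj, q_ri = constants$q_ri, dndc = dndc)
  if (is.null(dndc)) {
    dndc_src <- if (!is.null(inj) && inj$dndc_known) "given" else "estimated"
    dndc <- if (dndc_src == "given") inj$dndc
            else estimate_dndc(adj, inj, constants$q_ri)
  } else dndc_src <- "given"

  w <- weight_fractions(adj)
  # Slices within double-precision rounding of zero signal are always
  # masked: baseline subtraction leaves O(1e-13 mV) residues there whose
  # ratios are meaningless even for noise-free data.
  thr <- max(mask_threshold, 1e-12)
  masked <- !(adj$ad_ri >= thr * max(adj$ad_ri) &
                adj$ad_ri > 0 & conc > 0)
  m_lals <- slice_mw(adj, conc, constants, n1, dndc, "lals", setup = setup)
  m_rals <- slice_mw(adj, conc, constants, n1, dndc, "rals", setup = setup)
  eta <- slice_intrinsic_viscosity(adj$eta_sp, conc, visc_method)
  rg <- if (with_rg) slice_rg_from_ratio(adj, constants, setup) else NULL

  slices <- data.frame(vel = adj$vel, delta_vel = delta_vel(adj$vel),
                       c = as.numeric(conc), w = w,
                       x = NA_real_, m_lals = m_lals, m_rals = m_rals,
                       eta_sp = adj$eta_sp, eta_intr = as.numeric(eta),
                       masked = masked)
  if (!is.null(rg)) slices$rg <- rg
  for (col in c("m_lals", "m_rals", "eta_intr"))
    slices[[col]][masked] <- NA_real_
  if (!is.null(rg)) slices$rg[masked] <- NA_real_

  m_main <- slices[[paste0("m_", detector)]]
  keep <- !masked & is.finite(m_main) & is.finite(slices$eta_intr)
  if (!any(keep)) stop("no unmasked slices left to analyze")
  wk <- w[keep] / sum(w[keep])
  slices$x[keep] <- number_fractions(wk, m_main[keep])
  av <- mw_averages(wk, m_main[keep])
  eta_bulk <- bulk_intrinsic_viscosity(wk, slices$eta_intr[keep])

  # Error-propagated MHS weighting when the preprocessing stage measured
  # the detector noise levels (quiet-window residuals); otherwise plain.
  ns <- attr(adj, "noise_sd")
  ip_ref <- attr(adj, "ip_ref")
  ls_name <- if (detector == "lals") "lals" else "rals"
  mhs_var <- NULL
  if (!is.null(ns) && all(c("ri", ls_name, "ivdp") %in% names(ns)) &&
      all(is.finite(ns[c("ri", ls_name, "ivdp")])) &&
      !is.null(ip_ref) && is.finite(ip_ref) && ip_ref > 0) {
    ln10sq <- log(10)^2
    ls_sig <- if (detector == "lals") adj$ad_lals else adj$ad_rals
    dp_sig <- adj$eta_sp * ip_ref / 4
    rel_ls <- (ns[[ls_name]] / ls_sig)^2
    rel_ri <- (ns[["ri"]] / adj$ad_ri)^2
    rel_dp <- (ns[["ivdp"]] / dp_sig)^2
    mhs_var <- list(var_logm = (rel_ls + rel_ri) / ln10sq,
                    var_logeta = (rel_dp + rel_ri) / ln10sq,
                    cov_log = rel_ri / ln10sq)
  }
  mhs <- tryCatch(
    if (is.null(mhs_var))
      mhs_fit(m_main[keep], slices$eta_intr[keep])
    else
      mhs_fit(m_main[keep], slices$eta_intr[keep],
              var_logm = mhs_var$var_logm[keep],
              var_logeta = mhs_var$var_logeta[keep],
              cov_log = mhs_var$cov_log[keep]),
    error = function(e) NULL)

  # Recovered mass fraction: integral of slice concentration over the
  # injected mass (identically 1 for the mass-balance route).
  recovered <- if (!is.null(inj))
    sum(as.numeric(conc) * slices$delta_vel) / (inj$cin * inj$vin)
  else NA_real_

  summary <- structure(list(
    mn = av$mn, mw = av$mw, mz = av$mz, pdi = av$pdi,
    eta_bulk = eta_bulk, dndc_used = dndc, dndc_source = dndc_src,
    recovered_mass_fraction = recovered,
    analyzed_mass_fraction = sum(w[keep]),
    n_slices = nrow(slices), n_masked = sum(masked),
    detector = detector, visc_method = visc_method
  ), class = "sec_summary")

  class(slices) <- c("sec_slices", "data.frame")
  structure(list(slices = slices, summary = summary, mhs = mhs),
            class = "sec_analysis")
}

#' @export
print.sec_summary <- function(x, ...) {
  cat("md-SEC sample summary (", x$detector, " route)\n", sep = "")
  cat(sprintf("  Mn  = %.4g g/mol\n  Mw  = %.4g g/mol\n  Mz  = %.4g g/mol\n",
              x$mn, x$mw, x$mz))
  cat(sprintf("  PDI = %.3f\n  [eta]_bulk = %.4g mL/g (%s)\n",
              x$pdi, x$eta_bulk, x$visc_method))
  cat(sprintf("  dn/dc used = %.4g mL/g (%s)\n", x$dndc_used, x$dndc_source))
  if (is.finite(x$recovered_mass_fraction))
    cat(sprintf("  recovered mass fraction = %.4f\n", x$recovered_mass_fraction))
  cat(sprintf("  slices: %d (%d masked; analyzed mass fraction %.4f)\n",
              x$n_slices, x$n_masked, x$analyzed_mass_fraction))
  invisible(x)
}

#' @export
print.sec_analysis <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$mhs)) print(x$mhs)
  invisible(x)
}
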