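# Preprocessing: elution-region selection, baseline estimation/subtraction,
# peak normalization, and specific viscosity from the bridge viscometer.

#' Restrict a chromatogram to the elution region of interest
#'
#' Selects the elution-volume window that contains all significant peaks,
#' discarding instrumental artefacts outside it.  In `auto` mode the window
#' is the smallest contiguous range of slices whose smoothed RI trace rises
#' above 0.5% of its maximum excursion, padded by 10 slices on each side.
#' Smoothing (a centered 5-point moving median) is used only for this
#' detection step, never for the analyzed signals.
#'
#' @param raw A [sec_chromatogram()].
#' @param vmin,vmax Region bounds (mL), or both `NULL` for auto mode.
#' @return The restricted [sec_chromatogram()], with a `region` attribute.
#' @export
select_region <- function(raw, vmin = NULL, vmax = NULL) {
  stopifnot(inherits(raw, "sec_chromatogram"))
  if (is.null(vmin) != is.null(vmax))
    stop("give both 'vmin' and 'vmax', or neither for auto mode")
  if (is.null(vmin)) {
    sm <- stats::runmed(raw$ri, 5L)
    excess <- sm - min(sm)
    if (max(excess) <= 0) stop("auto region selection failed: flat RI trace")
    above <- which(excess > 0.005 * max(excess))
    lo <- max(1L, min(above) - 10L)
    hi <- min(nrow(raw), max(above) + 10L)
    keep <- lo:hi
  } else {
    if (vmin >= vmax) stop("'vmin' must be smaller than 'vmax'")
    keep <- which(raw$vel >= vmin & raw$vel <= vmax)
    if (length(keep) == 0L) stop("selected region contains no slices")
  }
  if (length(keep) < 3L) stop("selected region holds fewer than 3 slices")
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample") <- attr(raw, "sample")
  attr(out, "run_id") <- attr(raw, "run_id")
  attr(out, "region") <- range(out$vel)
  class(out) <- class(raw)
  out
}

#' Default quiet (solute-free) windows of a selected region
#'
#' The first and last `frac` of the selected elution range, used as the
#' solute-free flanks through which detector baselines are fitted.
#'
#' @param vel Elution-volume grid (mL).
#' @param frac Fraction of the range per flank (default 5%).
#' @return List with numeric length-2 elements `left` and `right` (mL).
#' @export
default_quiet_windows <- function(vel, frac = 0.05) {
  r <- range(vel)
  span <- diff(r)
  list(left = c(r[1], r[1] + frac * span),
       right = c(r[2] - frac * span, r[2]))
}

#' Fit a straight-line detector baseline through two quiet windows
#'
#' The baseline is the line through the (median Vel, median signal) point of
#' each quiet window.  Medians, rather than means, keep the fit robust to
#' residual spikes in the flanks.
#'
#' @param vel Elution-volume grid (mL).
#' @param y Signal trace (mV).
#' @param quiet_left,quiet_right Numeric length-2 windows (mL) on the flanks
#'   of the selected region; each must contain at least 5 grid points and
#'   they must not overlap.
#' @return An object of class `sec_baseline` with fields `slope` (mV/mL),
#'   `intercept` (mV) and `windows`.
#' @export
fit_baseline <- function(vel, y, quiet_left, quiet_right) {
  stopifnot(length(vel) == length(y))
  quiet_left <- as.numeric(quiet_left); quiet_right <- as.numeric(quiet_right)
  if (quiet_left[2] > quiet_right[1])
    stop("quiet windows overlap")
  idx_l <- which(vel >= quiet_left[1] & vel <= quiet_left[2])
  idx_r <- which(vel >= quiet_right[1] & vel <= quiet_right[2])
  if (length(idx_l) < 5L || length(idx_r) < 5L)
    stop("each quiet window must contain at least 5 grid points")
  x1 <- stats::median(vel[idx_l]); y1 <- stats::median(y[idx_l])
  x2 <- stats::median(vel[idx_r]); y2 <- stats::median(y[idx_r])
  slope <- (y2 - y1) / (x2 - x1)
  structure(
    list(slope = slope, intercept = y1 - slope * x1,
         windows = list(left = quiet_left, right = quiet_right)),
    class = "sec_baseline"
  )
}

#' Evaluate a fitted baseline on an elution grid
#' @param object A `sec_baseline` from [fit_baseline()].
#' @param vel Elution volumes (mL).
#' @param ... Unused.
#' @return Baseline values (mV).
#' @export
predict.sec_baseline <- function(object, vel, ...) {
  object$intercept + object$slope * vel
}

#' Subtract fitted baselines from the optical detector traces
#'
#' @param raw A region-restricted [sec_chromatogram()].
#' @param baselines Named list of `sec_baseline` objects for `ri`, `lals`
#'   and `rals` (optionally `ivdp`); missing entries leave the trace as is.
#' @return A [sec_adjusted()] (specific viscosity still `NA`; see
#'   [specific_viscosity()]).  The adjusted differential-pressure trace is
#'   attached as attribute `ad_dp` and the raw inlet pressure as `ip`.
#' @export
subtract_baseline <- function(raw, baselines) {
  stopifnot(inherits(raw, "sec_chromatogram"))
  bl <- function(name, y) {
    b <- baselines[[name]]
    if (is.null(b)) y else y - predict(b, raw$vel)
  }
  adj <- sec_adjusted(
    vel = raw$vel,
    ad_ri = bl("ri", raw$ri),
    ad_lals = bl("lals", raw$lals),
    ad_rals = bl("rals", raw$rals),
    region = attr(raw, "region") %||% range(raw$vel),
    sample = attr(raw, "sample") %||% ""
  )
  attr(adj, "ad_dp") <- bl("ivdp", raw$ivdp)
  attr(adj, "ip") <- raw$ivip
  adj
}

#' Specific viscosity from the bridge viscometer channels
#'
#' The Wheatstone-bridge viscometer reports a differential pressure DP that
#' measures the bridge imbalance caused by the solute, relative to the
#' absolute inlet pressure IP, giving the specific viscosity of the eluting
#' slice as `eta_sp = 4 * DP / IP`.  DP must be baseline-subtracted; IP must
#' be the raw (baseline-retained) absolute pressure, since the solvent-level
#' pressure is the physical denominator of the bridge relation --
#' subtracting the IP baseline would zero it.
#'
#' @param dp Baseline-adjusted differential pressure (mV).
#' @param ip Raw absolute inlet pressure (mV); slices with `ip <= 0` are
#'   flagged invalid and returned as `NA`.
#' @return Specific viscosity per slice (dimensionless).  The relative
#'   viscosity is `eta_sp + 1`.
#' @examples
#' specific_viscosity(1, 4)        # 1
#' specific_viscosity(0.05, 200)   # 1e-3
#' @export
specific_viscosity <- function(dp, ip) {
  stopifnot(length(dp) == length(ip))
  out <- ifelse(ip > 0, 4 * dp / ip, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)), " slice(s) with non-positive inlet pressure flagged invalid")
  out
}

#' Normalize detector traces to unit peak height
#'
#' Divides each trace by its maximum within the selected region, so all
#' maxima become exactly 1.  For a monodisperse sample, all normalized
#' optical traces superimpose.
#'
#' @param adj A [sec_adjusted()].
#' @param traces Which columns to normalize.
#' @return A data frame of normalized traces (same columns).
#' @export
normalize_to_unit_peak <- function(adj,
                                   traces = c("ad_ri", "ad_lals", "ad_rals",
                                              "eta_sp")) {
  out <- as.data.frame(adj)[traces]
  for (nm in traces) {
    m <- suppressWarnings(max(out[[nm]], na.rm = TRUE))
    if (!is.finite(m) || m <= 0)
      stop("cannot normalize all-zero (or negative) trace: ", nm)
    out[[nm]] <- out[[nm]] / m
  }
  out
}

#' Full preprocessing of a raw chromatogram
#'
#' Runs the standard preparation pipeline: region selection, straight-line
#' baseline fitting through the quiet flanks, baseline subtraction of the
#' RI/LALS/RALS/DP traces, and specific viscosity from the viscometer
#' bridge.  An optional per-detector elution-volume shift is available for
#' instruments with a non-negligible inter-detector delay (default 0; this
#' instrument class shows none).
#'
#' @param raw A [sec_chromatogram()].
#' @param vmin,vmax Region bounds (mL); both `NULL` for auto selection.
#' @param quiet_frac Fraction of the selected range per quiet flank.
#' @param shifts Named numeric vector of per-detector volume shifts (mL),
#'   e.g. `c(lals = 0.01)`; traces are interpolated back onto the common
#'   grid.
#' @return A [sec_adjusted()] with `eta_sp` filled in; fitted baselines are
#'   attached as attribute `baselines`.
#' @export
prepare_chromatogram <- function(raw, vmin = NULL, vmax = NULL,
                                 quiet_frac = 0.05, shifts = NULL) {
  stopifnot(inherits(raw, "sec_chromatogram"))
  if (!is.null(shifts)) {
    for (nm in names(shifts)) {
      if (!nm %in% c("ri", "lals", "rals", "ivdp", "ivip"))
        stop("unknown detector in 'shifts': ", nm)
      if (shifts[[nm]] != 0)
        raw[[nm]] <- stats::approx(raw$vel - shifts[[nm]], raw[[nm]],
                                   xout = raw$vel, rule = 2)$y
    }
  }
  sel <- select_region(raw, vmin, vmax)
  qw <- default_quiet_windows(sel$vel, quiet_frac)
  baselines <- lapply(
    stats::setNames(nm = c("ri", "lals", "rals", "ivdp")),
    function(nm) fit_baseline(sel$vel, sel[[nm]], qw$left, qw$right)
  )
  adj <- subtract_baseline(sel, baselines)
  adj$eta_sp <- specific_viscosity(attr(adj, "ad_dp"), attr(adj, "ip"))
  attr(adj, "baselines") <- baselines
  attr(adj, "quiet_windows") <- qw
  attr(adj, "noise_sd") <- estimate_noise_sd(sel, baselines, qw)
  attr(adj, "ip_ref") <- stats::median(sel$ivip)
  adj
}

#' Per-detector noise level from the quiet-window residuals
#'
#' The standard deviation of each detector trace about its fitted baseline,
#' over the quiet flanks only, estimates the detector's additive noise
#' level.  These estimates feed the error-propagated weighting of the
#' conformation fit in [mhs_fit()].
#'
#' @param raw A region-restricted [sec_chromatogram()].
#' @param baselines Named list of `sec_baseline` fits (`ri`, `lals`,
#'   `rals`, `ivdp`).
#' @param quiet_windows List with `left`/`right` windows (mL), as from
#'   [default_quiet_windows()].
#' @return Named numeric vector of noise standard deviations (mV).
#' @export
estimate_noise_sd <- function(raw, baselines, quiet_windows) {
  quiet <- (raw$vel >= quiet_windows$left[1] &
              raw$vel <= quiet_windows$left[2]) |
           (raw$vel >= quiet_windows$right[1] &
              raw$vel <= quiet_windows$right[2])
  vapply(stats::setNames(nm = names(baselines)), function(nm) {
    stats::sd(raw[[nm]][quiet] -
                predict(baselines[[nm]], raw$vel[quiet]))
  }, numeric(1))
}
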