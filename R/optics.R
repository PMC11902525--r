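# Scattering geometry: scattering vector, angular (form-factor) correction,
# and the validity test of the low-angle approximation.

#' Optical setup of the light-scattering detectors
#'
#' @param lambda0 Vacuum wavelength of the laser (nm); the instrument class
#'   modelled here uses 670 nm.
#' @param n Refractive index of the medium; for dilute aqueous solutions the
#'   solvent index (1.33) is used.
#' @param angles Detector angles (degrees), strictly inside (0, 180).
#' @return An object of class `optical_setup`.
#' @export
optical_setup <- function(lambda0 = 670, n = 1.33, angles = c(7, 90)) {
  if (!is.finite(lambda0) || lambda0 <= 0) stop("'lambda0' must be positive (nm)")
  if (!is.finite(n) || n < 1) stop("'n' must be >= 1")
  if (any(!is.finite(angles)) || any(angles <= 0 | angles >= 180))
    stop("detector angles must lie strictly between 0 and 180 degrees")
  structure(list(lambda0 = lambda0, n = n, angles = angles),
            class = "optical_setup")
}

#' Magnitude of the scattering vector
#'
#' `q = (4 * pi * n / lambda0) * sin(theta / 2)`, with the angle given in
#' degrees and `q` returned in 1/nm.
#'
#' @param setup An [optical_setup()].
#' @param theta Scattering angle (degrees), strictly inside (0, 180).
#' @return Scattering vector magnitude (nm^-1).
#' @examples
#' setup <- optical_setup(lambda0 = 632.8, n = 1.33)
#' scattering_vector(setup, 90)  # ~0.0187 nm^-1
#' scattering_vector(setup, 7)   # ~0.0016 nm^-1
#' @export
scattering_vector <- function(setup, theta) {
  stopifnot(inherits(setup, "optical_setup"))
  if (any(!is.finite(theta)) || any(theta <= 0 | theta >= 180))
    stop("'theta' must lie strictly between 0 and 180 degrees")
  (4 * pi * setup$n / setup$lambda0) * sin(theta * pi / 360)
}

#' Reciprocal form factor (angular correction term)
#'
#' The small-qRg expansion of the reciprocal particle form factor,
#' `1/P(theta) ~ 1 + q^2 Rg^2 / 3`.  The scattered intensity of a chain with
#' radius of gyration `rg` is attenuated by exactly this factor relative to
#' a point scatterer.
#'
#' @param q Scattering vector (nm^-1).
#' @param rg Radius of gyration (nm), non-negative.
#' @return Dimensionless correction factor, >= 1.
#' @export
angular_term <- function(q, rg) {
  if (any(!is.finite(q)) || any(q < 0)) stop("'q' must be non-negative")
  if (any(!is.finite(rg)) || any(rg < 0)) stop("'rg' must be non-negative")
  1 + q^2 * rg^2 / 3
}

#' Validity of the low-angle approximation
#'
#' The low-angle (LA) approximation treats the scatterer as point-like,
#' dropping the angular correction.  It is acceptable while `q^2 Rg^2 / 3`
#' stays well below unity; the conventional cutoff used here is 0.5.
#'
#' @param q Scattering vector (nm^-1).
#' @param rg Radius of gyration (nm).
#' @param threshold Acceptance cutoff on `q^2 Rg^2 / 3`.
#' @return List with `valid` (logical) and `value` (the `q^2 Rg^2 / 3` term).
#' @export
la_valid <- function(q, rg, threshold = 0.5) {
  value <- angular_term(q, rg) - 1
  list(valid = value < threshold, value = value)
}

#' Angular-correction report for a set of macromolecules
#'
#' Convenience tabulation of q and the `1 + q^2 Rg^2 / 3` term at each
#' detector angle for user-supplied (label, M, Rg) rows, in the style used
#' to judge the adequacy of low-angle and right-angle detection for common
#' polymer systems.
#'
#' @param rows Data frame with columns `label`, `m_kda`, `rg` (nm).
#' @param setup An [optical_setup()].
#' @return Data frame with one `term_<angle>` column per detector angle.
#' @export
angular_table <- function(rows, setup = optical_setup(lambda0 = 632.8)) {
  stopifnot(all(c("label", "rg") %in% names(rows)))
  out <- rows
  for (th in setup$angles) {
    q <- scattering_vector(setup, th)
    out[[sprintf("term_%g", th)]] <- angular_term(q, rows$rg)
  }
  attr(out, "q") <- stats::setNames(scattering_vector(setup, setup$angles),
                                    sprintf("%g", setup$angles))
  out
}
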