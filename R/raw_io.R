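#' @keywords internal
"_PACKAGE"

# Internal units contract (all conversions happen at the I/O boundary):
#   Vel in mL, c in g/mL, M in g/mol, [eta] in mL/g, lambda0 and Rg in nm,
#   q in nm^-1, detector signals in mV.

#' Injection and optical metadata for an md-SEC run
#'
#' Holds the quantities that drive mass conservation and the light-scattering
#' analysis: the injected volume and concentration, the refractive-index
#' increment of the solute, and the solvent refractive index.
#'
#' @param vin Injection volume (mL). Must be positive.
#' @param cin Concentration of the injected sample (g/mL). Must be positive.
#' @param dndc Refractive-index increment of the solute (mL/g). May be `NA`
#'   when unknown; it must then be estimated via [estimate_dndc()] before any
#'   light-scattering analysis.
#' @param n1 Refractive index of the solvent (dimensionless, > 1).
#' @return An object of class `sec_injection`.
#' @examples
#' injection_record(vin = 0.1, cin = 0.001, dndc = 0.145, n1 = 1.33)
#' @export
injection_record <- function(vin, cin, dndc = NA_real_, n1) {
  stopifnot(is.numeric(vin), length(vin) == 1L,
            is.numeric(cin), length(cin) == 1L,
            is.numeric(n1), length(n1) == 1L)
  if (!is.finite(vin) || vin <= 0) stop("'vin' must be a positive volume (mL)")
  if (!is.finite(cin) || cin <= 0) stop("'cin' must be a positive concentration (g/mL)")
  if (!is.finite(n1) || n1 <= 1) stop("'n1' must exceed 1 (solvent refractive index)")
  dndc <- as.numeric(dndc)
  if (length(dndc) != 1L) stop("'dndc' must be a single value or NA")
  if (!is.na(dndc) && dndc <= 0) stop("'dndc' must be positive when given")
  structure(
    list(vin = vin, cin = cin, dndc = dndc, n1 = n1,
         dndc_known = !is.na(dndc)),
    class = "sec_injection"
  )
}

#' @export
print.sec_injection <- function(x, ...) {
  cat("md-SEC injection record\n")
  cat(sprintf("  Vin   = %g mL\n", x$vin))
  cat(sprintf("  cin   = %g g/mL\n", x$cin))
  cat(sprintf("  dn/dc = %s\n",
              if (x$dndc_known) sprintf("%g mL/g", x$dndc) else "unknown"))
  cat(sprintf("  n1    = %g\n", x$n1))
  invisible(x)
}

raw_columns <- c("vel", "ri", "lals", "rals", "ivdp", "ivip")
adjusted_columns <- c("vel", "ad_ri", "ad_lals", "ad_rals", "eta_sp")

#' Raw multi-detector chromatogram
#'
#' A chromatogram is an elution-volume grid plus the five raw detector traces
#' in mV: refractive index (RI), low-angle light scattering (LALS),
#' right-angle light scattering (RALS), and the differential (IVDP) and
#' absolute/inlet (IVIP) pressures of the bridge viscometer.
#'
#' @param vel Elution volume grid (mL); strictly increasing, uniform spacing
#'   within 1% relative tolerance, length >= 3.
#' @param ri,lals,rals,ivdp,ivip Signal traces (mV), one value per grid point.
#' @param sample,run_id Optional labels.
#' @return A `data.frame` of class `sec_chromatogram` with columns
#'   `vel, ri, lals, rals, ivdp, ivip`.
#' @export
sec_chromatogram <- function(vel, ri, lals, rals, ivdp, ivip,
                             sample = "", run_id = "") {
  x <- data.frame(vel = as.numeric(vel), ri = as.numeric(ri),
                  lals = as.numeric(lals), rals = as.numeric(rals),
                  ivdp = as.numeric(ivdp), ivip = as.numeric(ivip))
  validate_vel_grid(x$vel)
  attr(x, "sample") <- as.character(sample)
  attr(x, "run_id") <- as.character(run_id)
  class(x) <- c("sec_chromatogram", "data.frame")
  x
}

validate_vel_grid <- function(vel) {
  if (length(vel) < 3L) stop("chromatogram needs at least 3 slices")
  if (anyNA(vel)) stop("elution-volume grid contains missing values")
  d <- diff(vel)
  if (any(d <= 0)) stop("elution volume must be strictly increasing")
  if (max(abs(d - mean(d))) / mean(d) > 0.01)
    stop("elution-volume grid spacing is not uniform (beyond 1% tolerance)")
  invisible(vel)
}

#' Baseline-adjusted chromatogram
#'
#' The product of the preprocessing stage: zero-baseline RI/LALS/RALS traces
#' restricted to the selected elution region, plus the per-slice specific
#' viscosity from the bridge viscometer.
#'
#' @param vel Elution-volume grid (mL) within the selected region.
#' @param ad_ri,ad_lals,ad_rals Baseline-subtracted traces (mV).
#' @param eta_sp Per-slice specific viscosity (dimensionless); may be `NA`
#'   before the viscometer channels have been combined.
#' @param region Numeric length-2 vector, the selected region bounds (mL).
#' @param sample Optional label.
#' @return A `data.frame` of class `sec_adjusted`.
#' @export
sec_adjusted <- function(vel, ad_ri, ad_lals, ad_rals,
                         eta_sp = rep(NA_real_, length(vel)),
                         region = range(vel), sample = "") {
  x <- data.frame(vel = as.numeric(vel), ad_ri = as.numeric(ad_ri),
                  ad_lals = as.numeric(ad_lals), ad_rals = as.numeric(ad_rals),
                  eta_sp = as.numeric(eta_sp))
  validate_vel_grid(x$vel)
  region <- as.numeric(region)
  if (length(region) != 2L || region[1] >= region[2])
    stop("'region' must be increasing bounds (mL)")
  attr(x, "region") <- region
  attr(x, "sample") <- as.character(sample)
  class(x) <- c("sec_adjusted", "data.frame")
  x
}

# ---- file dialect -----------------------------------------------------------
# '#'-prefixed header lines carry "key = value" metadata; the remainder is a
# plain numeric table, tab- or space-separated.  Human-editable and diff-able.

parse_header_meta <- function(lines) {
  hdr <- sub("^#\\s*", "", lines)
  kv <- regmatches(hdr, regexec("^([A-Za-z0-9_./-]+)\\s*=\\s*(.*)$", hdr))
  kv <- Filter(function(m) length(m) == 3L, kv)
  stats::setNames(vapply(kv, `[`, "", 3L), tolower(vapply(kv, `[`, "", 2L)))
}

read_numeric_table <- function(path, n_cols, col_names) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  meta <- parse_header_meta(lines[is_comment])
  body_idx <- which(!is_comment & !is_blank)
  if (length(body_idx) == 0L)
    stop("no data rows in ", path)
  fields <- strsplit(trimws(lines[body_idx]), "[\\s,]+", perl = TRUE)
  nf <- lengths(fields)
  if (any(nf != n_cols)) {
    bad <- body_idx[which(nf != n_cols)[1]]
    stop(sprintf("expected %d columns but found %d on line %d of %s",
                 n_cols, nf[which(nf != n_cols)[1]], bad, path))
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad_row <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad_row))
    stop(sprintf("non-numeric value on line %d of %s",
                 body_idx[bad_row[1]], path))
  tab <- as.data.frame(do.call(rbind, vals))
  names(tab) <- col_names
  list(meta = as.list(meta), data = tab)
}

fmt_num <- function(x) formatC(x, format = "e", digits = 9)

write_table_file <- function(path, meta, data) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s = %s", k, meta[[k]]), con)
  writeLines(paste0("# columns: ", paste(names(data), collapse = "\t")), con)
  body <- do.call(paste, c(lapply(data, fmt_num), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

# ---- readers / writers ------------------------------------------------------

#' Read an injection metadata file
#'
#' Parses a small key/value text file holding `Vin` (mL), `cin` (g/mL),
#' `dndc` (mL/g) and `n1`.  Lines may be `key = value` pairs, optionally
#' '#'-commented; keys are case-insensitive.  `dndc` may be given as
#' `unknown` (or `NA`), in which case the record is flagged and dn/dc must be
#' estimated from a calibrated RI detector before light-scattering analysis.
#'
#' @param path Path to the metadata file.
#' @return A [injection_record()] object.
#' @export
read_init <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^\\s*#\\s*", "", lines)
  lines <- lines[!grepl("^\\s*$", lines)]
  meta <- parse_header_meta(paste0("# ", lines))
  need <- c("vin", "cin", "n1")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys))
    stop("missing required field(s) in ", path, ": ",
         paste(missing_keys, collapse = ", "))
  num <- function(key) {
    v <- suppressWarnings(as.numeric(meta[[key]]))
    if (is.na(v))
      stop(sprintf("malformed value for '%s' in %s: '%s'",
                   key, path, meta[[key]]))
    v
  }
  dndc <- NA_real_
  if ("dndc" %in% names(meta)) {
    raw <- trimws(meta[["dndc"]])
    if (!tolower(raw) %in% c("unknown", "na", "nan", ""))
      dndc <- num("dndc")
  }
  injection_record(vin = num("vin"), cin = num("cin"),
                   dndc = dndc, n1 = num("n1"))
}

#' Write an injection metadata file
#' @param path Output path.
#' @param inj A [injection_record()] object.
#' @export
write_init <- function(path, inj) {
  stopifnot(inherits(inj, "sec_injection"))
  writeLines(c(
    "# md-SEC injection metadata",
    sprintf("Vin = %s", fmt_num(inj$vin)),
    sprintf("cin = %s", fmt_num(inj$cin)),
    sprintf("dndc = %s", if (inj$dndc_known) fmt_num(inj$dndc) else "unknown"),
    sprintf("n1 = %s", fmt_num(inj$n1))
  ), path)
  invisible(path)
}

#' Read a raw five-detector signal table
#'
#' Expects a whitespace- or comma-delimited table of six numeric columns in
#' the order `Vel, RI, LALS, RALS, IVDP, IVIP`; '#'-prefixed lines are
#' treated as comments (and may carry `key = value` metadata such as the
#' sample name).  A column-order override is available for exports from
#' other instrument software.
#'
#' @param path Path to the signal file.
#' @param columns Character vector naming the on-disk column order; a
#'   permutation of `c("vel","ri","lals","rals","ivdp","ivip")`.
#' @return A [sec_chromatogram()].
#' @export
read_raw_signals <- function(path, columns = raw_columns) {
  if (!setequal(columns, raw_columns) || length(columns) != 6L)
    stop("'columns' must be a permutation of: ",
         paste(raw_columns, collapse = ", "))
  parsed <- read_numeric_table(path, 6L, columns)
  d <- parsed$data[raw_columns]
  sec_chromatogram(d$vel, d$ri, d$lals, d$rals, d$ivdp, d$ivip,
                   sample = parsed$meta[["sample"]] %||% "",
                   run_id = parsed$meta[["run_id"]] %||% "")
}

#' Write a raw five-detector signal table
#' @param path Output path.
#' @param raw A [sec_chromatogram()].
#' @export
write_raw_signals <- function(path, raw) {
  stopifnot(inherits(raw, "sec_chromatogram"))
  meta <- c(sample = attr(raw, "sample") %||% "",
            run_id = attr(raw, "run_id") %||% "")
  meta <- meta[nzchar(meta)]
  write_table_file(path, as.list(meta), as.data.frame(raw)[raw_columns])
}

#' Write a baseline-adjusted chromatogram file
#'
#' Values are written with 10 significant digits so that a write/read round
#' trip is lossless to well below instrumental precision.
#'
#' @param path Output path.
#' @param adj A [sec_adjusted()] object.
#' @export
write_adjusted <- function(path, adj) {
  stopifnot(inherits(adj, "sec_adjusted"))
  region <- attr(adj, "region")
  meta <- list(sample = attr(adj, "sample") %||% "",
               region = paste(fmt_num(region), collapse = " "))
  ns <- attr(adj, "noise_sd")
  if (!is.null(ns) && all(is.finite(ns)))
    meta$noise_sd <- paste(names(ns), fmt_num(ns), collapse = " ")
  ipr <- attr(adj, "ip_ref")
  if (!is.null(ipr) && is.finite(ipr)) meta$ip_ref <- fmt_num(ipr)
  meta <- meta[vapply(meta, nzchar, logical(1))]
  write_table_file(path, meta, as.data.frame(adj)[adjusted_columns])
}

#' Read a baseline-adjusted chromatogram file
#' @param path Path written by [write_adjusted()].
#' @return A [sec_adjusted()] object.
#' @export
read_adjusted <- function(path) {
  parsed <- read_numeric_table(path, 5L, adjusted_columns)
  d <- parsed$data
  region <- if (!is.null(parsed$meta[["region"]])) {
    as.numeric(strsplit(trimws(parsed$meta[["region"]]), "\\s+")[[1]])
  } else range(d$vel)
  adj <- sec_adjusted(d$vel, d$ad_ri, d$ad_lals, d$ad_rals, d$eta_sp,
                      region = region,
                      sample = parsed$meta[["sample"]] %||% "")
  ns_raw <- parsed$meta[["noise_sd"]]
  if (!is.null(ns_raw)) {
    tok <- strsplit(trimws(ns_raw), "\\s+")[[1]]
    if (length(tok) %% 2L == 0L && length(tok) > 0L) {
      idx <- seq(1L, length(tok), by = 2L)
      attr(adj, "noise_sd") <- stats::setNames(as.numeric(tok[idx + 1L]),
                                               tok[idx])
    }
  }
  ipr <- parsed$meta[["ip_ref"]]
  if (!is.null(ipr)) attr(adj, "ip_ref") <- as.numeric(ipr)
  adj
}

`%||%` <- function(a, b)
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# Forward slice widths; the final slice reuses the previous width.
delta_vel <- function(vel) {
  d <- diff(vel)
  c(d, d[length(d)])
}
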