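#' Unit conversions for urological hydraulics
#'
#' The package computes internally in SI units (m, Pa, Pa.s, m^3/s, s).
#' Clinical literature quotes catheter sizes in French gauge (3 Fr = 1 mm),
#' pressures in cm H2O (1 cm H2O = 98.1 Pa), viscosities in centipoise and
#' flow rates in mL/min or mL/s; these helpers convert at the boundaries.
#'
#' @param size catheter size in French gauge (Fr); must be non-negative.
#' @return `french_to_meters()`: diameter in metres.
#' @examples
#' french_to_meters(7.5)           # 2.5 mm scope shaft
#' meters_to_french(1e-3)          # 3 Fr
#' cmH2O_to_Pa(40)                 # backflow threshold in Pa
#' @export
french_to_meters <- function(size) {
  if (any(!is.finite(size)) || any(size < 0)) {
    stop("French gauge size must be finite and non-negative", call. = FALSE)
  }
  size / 3 * 1e-3
}

#' @rdname french_to_meters
#' @param d diameter in metres; must be non-negative.
#' @export
meters_to_french <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("diameter must be finite and non-negative", call. = FALSE)
  }
  d * 3e3
}

#' @rdname french_to_meters
#' @param p pressure in cm H2O (gauge pressures may be zero or negative).
#' @export
cmH2O_to_Pa <- function(p) p * 98.1

#' @rdname french_to_meters
#' @param pa pressure in Pa.
#' @export
Pa_to_cmH2O <- function(pa) pa / 98.1

#' @rdname french_to_meters
#' @param k renal pelvis stiffness in cm H2O per mL.
#' @export
cmH2O_per_mL_to_Pa_per_m3 <- function(k) k * 98.1 / 1e-6

#' @rdname french_to_meters
#' @param q flow rate in mL per minute.
#' @export
mL_per_min_to_m3_per_s <- function(q) q * 1e-6 / 60

#' @rdname french_to_meters
#' @export
mL_per_s_to_m3_per_s <- function(q) q * 1e-6

# one linear factor per accepted unit string, keyed by physical dimension
.unit_table <- list(
  length    = c(m = 1, cm = 1e-2, mm = 1e-3, Fr = 1e-3 / 3, F = 1e-3 / 3),
  pressure  = c(Pa = 1, kPa = 1e3, cmH2O = 98.1),
  viscosity = c("Pa.s" = 1, "Pa*s" = 1, cP = 1e-3),
  flow      = c("m3/s" = 1, "mL/s" = 1e-6, "mL/min" = 1e-6 / 60),
  stiffness = c("Pa/m3" = 1, "cmH2O/mL" = 98.1e6),
  time      = c(s = 1, min = 60, h = 3600)
)

#' Parse a quantity string with units into SI
#'
#' Configuration files state units per field (e.g. `"7.5 Fr"`, `"150 cmH2O"`,
#' `"1 cP"`, `"0.4 cmH2O/mL"`, `"20 min"`). The value is converted to SI for
#' the stated physical dimension; a bare number is accepted only when already
#' in SI and `allow_bare = TRUE`.
#'
#' @param x a string like `"150 cmH2O"` or a bare number.
#' @param dimension one of `"length"`, `"pressure"`, `"viscosity"`, `"flow"`,
#'   `"stiffness"`, `"time"`.
#' @param allow_bare accept a unitless number as already-SI.
#' @return numeric scalar in SI units.
#' @examples
#' parse_quantity("7.5 Fr", "length")    # 0.0025 m
#' parse_quantity("150 cmH2O", "pressure")
#' @export
parse_quantity <- function(x, dimension, allow_bare = TRUE) {
  dimension <- match.arg(dimension, names(.unit_table))
  units <- .unit_table[[dimension]]
  if (is.numeric(x)) {
    if (!allow_bare) stop("a unit is required for ", dimension, call. = FALSE)
    return(as.numeric(x))
  }
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([-+0-9.eE]+)\\s*(.*)$", x))[[1]]
  if (length(m) != 3 || m[2] == "") {
    stop("cannot parse quantity: '", x, "'", call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(m[2]))
  unit <- gsub("\\s+", "", m[3])
  if (is.na(value)) stop("cannot parse number in '", x, "'", call. = FALSE)
  if (unit == "") {
    if (!allow_bare) stop("a unit is required for ", dimension, call. = FALSE)
    return(value)
  }
  if (!unit %in% names(units)) {
    stop("unknown ", dimension, " unit '", unit, "' in '", x, "'; accepted: ",
         paste(names(units), collapse = ", "), call. = FALSE)
  }
  value * units[[unit]]
}
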