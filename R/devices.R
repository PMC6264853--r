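#' Irrigation fluid properties
#'
#' Saline irrigant and urine behave as Newtonian fluids; the only property
#' the Poiseuille model needs is the dynamic viscosity, approximately
#' 1 cP (1e-3 Pa.s) for saline at body temperature.
#'
#' @param viscosity dynamic viscosity in Pa.s; must be positive.
#' @return an object of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity = 1e-3) {
  if (!is.numeric(viscosity) || length(viscosity) != 1 || !is.finite(viscosity) ||
      viscosity <= 0) {
    stop("viscosity must be a single positive number [Pa.s]", call. = FALSE)
  }
  structure(list(viscosity = viscosity), class = "fluid_properties")
}

.check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(nm, " must be a single positive number", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Ureteroscope geometry
#'
#' A flexible or semirigid ureteroscope is modelled as a uniform cylinder at
#' its tip diameter, with a circular irrigation working channel running its
#' working length.
#'
#' @param shaft_diameter outer shaft diameter in m.
#' @param channel_diameter irrigation working-channel diameter in m; must be
#'   smaller than the shaft diameter.
#' @param working_length working length in m.
#' @param label optional device label.
#' @return an object of class `ureteroscope`.
#' @seealso [default_ureteroscope()] for the benchmark flexible scope.
#' @export
ureteroscope <- function(shaft_diameter, channel_diameter, working_length,
                         label = "ureteroscope") {
  .check_positive(shaft_diameter = shaft_diameter,
                  channel_diameter = channel_diameter,
                  working_length = working_length)
  if (channel_diameter >= shaft_diameter) {
    stop("channel_diameter must be smaller than shaft_diameter", call. = FALSE)
  }
  structure(list(shaft_diameter = shaft_diameter,
                 channel_diameter = channel_diameter,
                 working_length = working_length,
                 label = label),
            class = "ureteroscope")
}

#' @describeIn ureteroscope the Karl Storz Flex-X2 benchmark: 7.5 Fr tip,
#'   3.6 Fr working channel, 67 cm working length.
#' @export
default_ureteroscope <- function() {
  ureteroscope(shaft_diameter = french_to_meters(7.5),
               channel_diameter = french_to_meters(3.6),
               working_length = 0.67,
               label = "Flex-X2 7.5 Fr")
}

#' Ureteral access sheath
#'
#' Sheaths are sold under dual labels such as "10/12 Fr": 10 Fr inner lumen /
#' 12 Fr outer diameter. The inner lumen governs the annular outflow around
#' the scope, so only the inner diameter and length enter the model.
#'
#' @param inner_diameter lumen diameter in m.
#' @param length sheath length in m (35 cm typical).
#' @param label optional label, e.g. `"10/12 Fr"`.
#' @return an object of class `access_sheath`.
#' @export
access_sheath <- function(inner_diameter, length = 0.35, label = NULL) {
  .check_positive(inner_diameter = inner_diameter, length = length)
  if (is.null(label)) {
    label <- sprintf("%g Fr lumen", meters_to_french(inner_diameter))
  }
  structure(list(inner_diameter = inner_diameter, length = length,
                 label = label),
            class = "access_sheath")
}

#' @describeIn access_sheath build a sheath from its clinical dual-size label
#'   (`"10/12"`, `"10/12 Fr"`): inner lumen = first number, in Fr.
#' @param x a label string such as `"10/12 Fr"`.
#' @export
sheath_from_label <- function(x, length = 0.35) {
  m <- regmatches(x, regexec("^\\s*([0-9.]+)\\s*/\\s*([0-9.]+)", x))[[1]]
  if (length(m) != 3) stop("cannot parse sheath label '", x, "'", call. = FALSE)
  inner <- as.numeric(m[2])
  outer <- as.numeric(m[3])
  if (inner >= outer) stop("sheath label '", x, "' has inner >= outer", call. = FALSE)
  access_sheath(french_to_meters(inner), length,
                label = sprintf("%g/%g Fr", inner, outer))
}

#' Upper urinary tract anatomy
#'
#' Relaxed (nominal) dimensions of the ureteropelvic junction (UPJ) and
#' ureter, plus the linear renal pelvis stiffness K of the constitutive
#' relation dP = K dV. While the scope is inserted, the UPJ and ureter are
#' distended; their stretched diameters are taken as fixed multiples of the
#' scope shaft diameter (defaults 1.11 for the UPJ and 1.14 for the ureter,
#' calibrated against ex-vivo porcine pressure data).
#'
#' @param upj_diameter relaxed UPJ diameter in m (nominal 1.3 Fr, from the
#'   Whitaker-test inversion, see [whitaker_upj_diameter()]).
#' @param upj_length UPJ conduit length in m (0.5 cm).
#' @param ureter_diameter relaxed ureter diameter in m (8.5 Fr).
#' @param ureter_length ureter length in m (25 cm).
#' @param upj_stretch,ureter_stretch distension factors applied to the scope
#'   shaft diameter while inserted; must be >= 1.
#' @param stiffness renal pelvis stiffness K in Pa/m^3 (0.4 cmH2O/mL default).
#' @return an object of class `anatomy`.
#' @export
anatomy <- function(upj_diameter = french_to_meters(1.3),
                    upj_length = 0.005,
                    ureter_diameter = french_to_meters(8.5),
                    ureter_length = 0.25,
                    upj_stretch = 1.11,
                    ureter_stretch = 1.14,
                    stiffness = cmH2O_per_mL_to_Pa_per_m3(0.4)) {
  .check_positive(upj_diameter = upj_diameter, upj_length = upj_length,
                  ureter_diameter = ureter_diameter, ureter_length = ureter_length,
                  stiffness = stiffness)
  if (!is.numeric(upj_stretch) || upj_stretch < 1 ||
      !is.numeric(ureter_stretch) || ureter_stretch < 1) {
    stop("stretch factors must be >= 1", call. = FALSE)
  }
  structure(list(upj_diameter = upj_diameter, upj_length = upj_length,
                 ureter_diameter = ureter_diameter, ureter_length = ureter_length,
                 upj_stretch = upj_stretch, ureter_stretch = ureter_stretch,
                 stiffness = stiffness),
            class = "anatomy")
}

#' @describeIn anatomy the representative adult anatomy used throughout.
#' @export
default_anatomy <- function() anatomy()

#' Whitaker-test operating point
#'
#' A Whitaker test perfuses the upper urinary tract at a known flow rate and
#' records the renal pelvis-to-bladder pressure difference. For an
#' unobstructed tract the operating point is roughly 15 cm H2O at 15 mL/min;
#' inverting Poiseuille's law at this point yields an effective nominal UPJ
#' diameter.
#'
#' @param pressure_drop pressure difference across the tract in Pa; > 0.
#' @param flow_rate perfusion flow rate in m^3/s; > 0.
#' @return an object of class `whitaker_measurement`.
#' @export
whitaker_measurement <- function(pressure_drop, flow_rate) {
  .check_positive(pressure_drop = pressure_drop, flow_rate = flow_rate)
  structure(list(pressure_drop = pressure_drop, flow_rate = flow_rate),
            class = "whitaker_measurement")
}

#' @export
print.ureteroscope <- function(x, ...) {
  cat(sprintf("<ureteroscope> %s: shaft %.2f Fr, channel %.2f Fr, length %.0f cm\n",
              x$label, meters_to_french(x$shaft_diameter),
              meters_to_french(x$channel_diameter), 100 * x$working_length))
  invisible(x)
}

#' @export
print.access_sheath <- function(x, ...) {
  cat(sprintf("<access_sheath> %s: lumen %.2f Fr, length %.0f cm\n",
              x$label, meters_to_french(x$inner_diameter), 100 * x$length))
  invisible(x)
}

#' @export
print.anatomy <- function(x, ...) {
  cat(sprintf(paste0("<anatomy> UPJ %.2f Fr x %.1f cm, ureter %.2f Fr x %.0f cm, ",
                     "stretch %.2f/%.2f, K %.2f cmH2O/mL\n"),
              meters_to_french(x$upj_diameter), 100 * x$upj_length,
              meters_to_french(x$ureter_diameter), 100 * x$ureter_length,
              x$upj_stretch, x$ureter_stretch,
              x$stiffness * 1e-6 / 98.1))
  invisible(x)
}
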