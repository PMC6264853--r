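#' Poiseuille resistance of a circular conduit
#'
#' Laminar, quasi-static, fully developed flow through a cylindrical tube of
#' length l and diameter d obeys dP = R Q with R = 128 mu l / (pi d^4).
#'
#' @param length conduit length in m; > 0.
#' @param diameter conduit diameter in m; > 0.
#' @param viscosity dynamic viscosity in Pa.s; > 0.
#' @return hydraulic resistance in Pa.s/m^3.
#' @examples
#' # a 3.6 Fr working channel over a 67 cm scope, saline
#' circular_resistance(0.67, french_to_meters(3.6), 1e-3)
#' @export
circular_resistance <- function(length, diameter, viscosity) {
  .check_positive(length = length, diameter = diameter, viscosity = viscosity)
  128 * viscosity * length / (pi * diameter^4)
}

#' Effective fourth-power diameter of an annulus
#'
#' For pressure-driven laminar flow in the annular gap between an outer wall
#' of diameter `d_outer` and an inner cylinder of diameter `d_inner`, the
#' circular-tube resistance formula applies with d^4 replaced by
#' \deqn{\tilde d^4 = d_o^4 - d_i^4 - (d_o^2 - d_i^2)^2 / \ln(d_o/d_i).}
#' The expression is strictly positive for `d_outer > d_inner > 0`, increases
#' with `d_outer`, tends to `d_outer^4` as the inner cylinder vanishes and to
#' zero as the gap closes.
#'
#' @param d_outer outer diameter in m.
#' @param d_inner inner diameter in m; `0 <= d_inner < d_outer`.
#' @return effective diameter to the fourth power, in m^4.
#' @export
annular_effective_d4 <- function(d_outer, d_inner) {
  .check_positive(d_outer = d_outer)
  if (!is.numeric(d_inner) || length(d_inner) != 1 || !is.finite(d_inner) ||
      d_inner < 0) {
    stop("d_inner must be a single non-negative number", call. = FALSE)
  }
  if (d_inner >= d_outer) {
    stop("degenerate annulus: d_inner (", d_inner, ") must be < d_outer (",
         d_outer, ")", call. = FALSE)
  }
  if (d_inner == 0) return(d_outer^4)
  d_outer^4 - d_inner^4 - (d_outer^2 - d_inner^2)^2 / log(d_outer / d_inner)
}

#' Poiseuille resistance of an annular conduit
#'
#' @inheritParams circular_resistance
#' @inheritParams annular_effective_d4
#' @return hydraulic resistance in Pa.s/m^3.
#' @seealso [annular_effective_d4()]
#' @export
annular_resistance <- function(length, d_outer, d_inner, viscosity) {
  .check_positive(length = length, viscosity = viscosity)
  128 * viscosity * length / (pi * annular_effective_d4(d_outer, d_inner))
}

#' Distended diameter of a compliant conduit around the scope
#'
#' While the ureteroscope is inserted the UPJ and ureter wrap around the
#' shaft; their distended diameters are modelled as a fixed multiple of the
#' shaft diameter (ureter 14% larger, UPJ 11% larger by default).
#'
#' @param shaft_diameter scope shaft diameter in m.
#' @param stretch dimensionless distension factor; must be >= 1.
#' @return distended outer diameter in m.
#' @export
stretched_diameter <- function(shaft_diameter, stretch) {
  .check_positive(shaft_diameter = shaft_diameter)
  if (!is.numeric(stretch) || length(stretch) != 1 || !is.finite(stretch) ||
      stretch < 1) {
    stop("stretch must be a single number >= 1", call. = FALSE)
  }
  shaft_diameter * stretch
}

#' Hydraulic resistances of the irrigation circuit
#'
#' `inflow_resistance()` is the circular resistance of the scope's working
#' channel. `outflow_resistance()` is the series sum of the annular UPJ
#' segment (distended UPJ around the shaft) and the annular sheath segment
#' (sheath lumen around the shaft), or the annular ureter segment when no
#' sheath is used. `withdrawal_resistance()` applies after the scope is
#' removed: the same segments become circular at their nominal (relaxed)
#' diameters.
#'
#' @param scope a [ureteroscope()].
#' @param anat an [anatomy()].
#' @param sheath an [access_sheath()], or `NULL` for sheathless procedures.
#' @param fluid a [fluid_properties()].
#' @return hydraulic resistance in Pa.s/m^3.
#' @examples
#' mu <- fluid_properties()
#' inflow_resistance(default_ureteroscope(), mu)
#' outflow_resistance(default_ureteroscope(), default_anatomy(),
#'                    sheath_from_label("10/12 Fr"), mu)
#' @export
inflow_resistance <- function(scope, fluid = fluid_properties()) {
  stopifnot(inherits(scope, "ureteroscope"), inherits(fluid, "fluid_properties"))
  circular_resistance(scope$working_length, scope$channel_diameter,
                      fluid$viscosity)
}

#' @rdname inflow_resistance
#' @export
outflow_resistance <- function(scope, anat, sheath = NULL,
                               fluid = fluid_properties()) {
  stopifnot(inherits(scope, "ureteroscope"), inherits(anat, "anatomy"),
            inherits(fluid, "fluid_properties"))
  d_sc <- scope$shaft_diameter
  d_upj <- stretched_diameter(d_sc, anat$upj_stretch)
  if (d_upj <= d_sc) {
    stop("distended UPJ diameter does not clear the scope shaft", call. = FALSE)
  }
  r_upj <- annular_resistance(anat$upj_length, d_upj, d_sc, fluid$viscosity)
  if (is.null(sheath)) {
    d_ur <- stretched_diameter(d_sc, anat$ureter_stretch)
    r_drain <- annular_resistance(anat$ureter_length, d_ur, d_sc, fluid$viscosity)
  } else {
    stopifnot(inherits(sheath, "access_sheath"))
    if (sheath$inner_diameter <= d_sc) {
      stop("sheath lumen (", sheath$label, ") does not clear the scope shaft",
           call. = FALSE)
    }
    r_drain <- annular_resistance(sheath$length, sheath$inner_diameter, d_sc,
                                  fluid$viscosity)
  }
  r_upj + r_drain
}

#' @rdname inflow_resistance
#' @export
withdrawal_resistance <- function(anat, sheath = NULL,
                                  fluid = fluid_properties()) {
  stopifnot(inherits(anat, "anatomy"), inherits(fluid, "fluid_properties"))
  r_upj <- circular_resistance(anat$upj_length, anat$upj_diameter,
                               fluid$viscosity)
  if (is.null(sheath)) {
    r_drain <- circular_resistance(anat$ureter_length, anat$ureter_diameter,
                                   fluid$viscosity)
  } else {
    stopifnot(inherits(sheath, "access_sheath"))
    r_drain <- circular_resistance(sheath$length, sheath$inner_diameter,
                                   fluid$viscosity)
  }
  r_upj + r_drain
}

#' Bundle of the three circuit resistances
#'
#' @param inflow,outflow,withdrawal resistances in Pa.s/m^3; all > 0.
#' @return an object of class `resistance_set`.
#' @export
resistance_set <- function(inflow, outflow, withdrawal) {
  .check_positive(inflow = inflow, outflow = outflow, withdrawal = withdrawal)
  structure(list(inflow = inflow, outflow = outflow, withdrawal = withdrawal),
            class = "resistance_set")
}

#' @describeIn resistance_set compute all three resistances for a device and
#'   anatomy configuration.
#' @inheritParams inflow_resistance
#' @param anat an [anatomy()].
#' @param sheath an [access_sheath()] or `NULL`.
#' @export
compute_resistances <- function(scope, anat, sheath = NULL,
                                fluid = fluid_properties()) {
  resistance_set(inflow = inflow_resistance(scope, fluid),
                 outflow = outflow_resistance(scope, anat, sheath, fluid),
                 withdrawal = withdrawal_resistance(anat, sheath, fluid))
}

#' @export
print.resistance_set <- function(x, ...) {
  cat(sprintf("<resistance_set> Rin %.3e, Rout %.3e, Rw %.3e Pa.s/m^3\n",
              x$inflow, x$outflow, x$withdrawal))
  invisible(x)
}

#' Effective UPJ diameter from a Whitaker-test operating point
#'
#' Treating the upper tract as a single circular Poiseuille conduit of length
#' `upj_length`, the measured resistance R = dP/Q inverts to
#' d = (128 mu l Q / (pi dP))^(1/4). With the standard unobstructed operating
#' point (15 cm H2O at 15 mL/min) this yields about 1.3 Fr. Note that the
#' same pressure drop at 15 mL/s would give about 3.6 Fr: the quarter-power
#' makes the estimate insensitive, but the flow-rate unit matters and the
#' clinical operating point is conventionally quoted per minute.
#'
#' @param measurement a [whitaker_measurement()].
#' @param upj_length conduit length in m.
#' @param fluid a [fluid_properties()].
#' @return effective nominal diameter in m.
#' @examples
#' m <- whitaker_measurement(cmH2O_to_Pa(15), mL_per_min_to_m3_per_s(15))
#' meters_to_french(whitaker_upj_diameter(m, 0.005))  # ~1.3 Fr
#' @export
whitaker_upj_diameter <- function(measurement, upj_length,
                                  fluid = fluid_properties()) {
  stopifnot(inherits(measurement, "whitaker_measurement"),
            inherits(fluid, "fluid_properties"))
  .check_positive(upj_length = upj_length)
  (128 * fluid$viscosity * upj_length * measurement$flow_rate /
     (pi * measurement$pressure_drop))^0.25
}
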