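#' Scenario configurations
#'
#' A scenario bundles a device set, anatomy, irrigation pressure and initial
#' pressure, plus an optional ureteral stone location for procedures where
#' the scope stops in the ureter rather than entering the renal pelvis.
#'
#' @param label scenario label.
#' @param scope a [ureteroscope()].
#' @param anat an [anatomy()].
#' @param sheath an [access_sheath()] or `NULL`.
#' @param irrigation_pressure irrigation pressure in Pa.
#' @param initial_pressure initial gauge pressure in Pa.
#' @param stone_location distance of the stone from the ureteral orifice
#'   (bladder end, increasing proximally) in m, or `NULL` for renal stones;
#'   must not exceed the ureter length.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(label, scope = default_ureteroscope(),
                            anat = default_anatomy(), sheath = NULL,
                            irrigation_pressure = cmH2O_to_Pa(150),
                            initial_pressure = 0, stone_location = NULL) {
  stopifnot(inherits(scope, "ureteroscope"), inherits(anat, "anatomy"))
  if (!is.null(sheath)) stopifnot(inherits(sheath, "access_sheath"))
  if (!is.null(stone_location)) {
    .check_positive(stone_location = stone_location)
    if (stone_location > anat$ureter_length) {
      stop("stone_location exceeds the ureter length", call. = FALSE)
    }
  }
  structure(list(label = label, scope = scope, anat = anat, sheath = sheath,
                 irrigation_pressure = irrigation_pressure,
                 initial_pressure = initial_pressure,
                 stone_location = stone_location),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s: P_irr %.0f cmH2O, P_0 %.0f cmH2O, %s%s\n",
              x$label, Pa_to_cmH2O(x$irrigation_pressure),
              Pa_to_cmH2O(x$initial_pressure),
              if (is.null(x$sheath)) "no sheath" else x$sheath$label,
              if (is.null(x$stone_location)) "" else
                sprintf(", stone at %.0f cm", 100 * x$stone_location)))
  invisible(x)
}

#' Additional outflow resistance for a stone in the ureter
#'
#' When the target stone sits in the ureter the scope is only advanced as
#' far as the stone, and the irrigant returns through the annular gap
#' between the distended ureter and the scope over that inserted length.
#' The resistance is linear in the stone's distance from the ureteral
#' orifice and, for a stone at the proximal end, equals the full sheathless
#' ureter segment of the outflow path.
#'
#' @param stone_location distance from the ureteral orifice in m;
#'   `0 < stone_location <= ureter length`.
#' @param scope a [ureteroscope()].
#' @param anat an [anatomy()].
#' @param fluid a [fluid_properties()].
#' @return hydraulic resistance in Pa.s/m^3.
#' @export
stone_path_resistance <- function(stone_location, scope, anat,
                                  fluid = fluid_properties()) {
  stopifnot(inherits(scope, "ureteroscope"), inherits(anat, "anatomy"))
  .check_positive(stone_location = stone_location)
  if (stone_location > anat$ureter_length) {
    stop("stone_location exceeds the ureter length", call. = FALSE)
  }
  d_ur <- stretched_diameter(scope$shaft_diameter, anat$ureter_stretch)
  annular_resistance(stone_location, d_ur, scope$shaft_diameter,
                     fluid$viscosity)
}

#' Circuit parameters for a scenario
#'
#' Builds the [resistance_set()] and [circuit_parameters()] implied by a
#' scenario. For ureteral-stone scenarios the sheathless ureter return
#' segment spans only the inserted length up to the stone.
#'
#' @param scenario a [scenario_config()].
#' @param fluid a [fluid_properties()].
#' @return a [circuit_parameters()].
#' @export
scenario_parameters <- function(scenario, fluid = fluid_properties()) {
  stopifnot(inherits(scenario, "scenario_config"))
  sc <- scenario$scope; an <- scenario$anat
  if (is.null(scenario$stone_location)) {
    r_out <- outflow_resistance(sc, an, scenario$sheath, fluid)
  } else {
    d_upj <- stretched_diameter(sc$shaft_diameter, an$upj_stretch)
    r_out <- annular_resistance(an$upj_length, d_upj, sc$shaft_diameter,
                                fluid$viscosity) +
      stone_path_resistance(scenario$stone_location, sc, an, fluid)
  }
  res <- resistance_set(inflow = inflow_resistance(sc, fluid),
                        outflow = r_out,
                        withdrawal = withdrawal_resistance(an, scenario$sheath,
                                                           fluid))
  circuit_parameters(res, an$stiffness, scenario$irrigation_pressure,
                     scenario$initial_pressure)
}

#' The eight-curve sheath/irrigation-pressure comparison set
#'
#' Four sheath choices (no sheath, 10/12, 12/14 and 14/16 Fr) crossed with
#' two irrigation pressures (150 and 200 cm H2O), with the benchmark
#' flexible scope, representative anatomy and zero initial pressure. In
#' nondimensional variables (pressure over irrigation pressure, time over
#' rise time) the eight curves collapse onto four, one per sheath choice.
#'
#' @param irrigation_pressures irrigation pressures in Pa.
#' @param sheath_labels sheath labels, `NA` meaning no sheath.
#' @return a list of [scenario_config()] objects.
#' @export
sheath_comparison_scenarios <- function(
    irrigation_pressures = cmH2O_to_Pa(c(150, 200)),
    sheath_labels = c(NA, "10/12", "12/14", "14/16")) {
  out <- list()
  for (sh in sheath_labels) {
    sheath <- if (is.na(sh)) NULL else sheath_from_label(sh)
    for (p in irrigation_pressures) {
      lbl <- sprintf("%s, %.0f cmH2O",
                     if (is.na(sh)) "no sheath" else paste0(sh, " Fr"),
                     Pa_to_cmH2O(p))
      out[[length(out) + 1]] <- scenario_config(lbl, sheath = sheath,
                                                irrigation_pressure = p)
    }
  }
  out
}

#' The thirteen published-study validation scenarios
#'
#' Reconstructs the conditions of the two clinical data sets the model was
#' validated against: four flexible-scope runs after Rehman et al. (Flex-X2
#' at 200 cm H2O; no sheath plus three sheath sizes, zero baseline) and nine
#' semirigid runs after Shao et al. (Wolf 8/9.8 Fr scope, ureteral stones at
#' three locations crossed with three irrigation pressures, nonzero
#' baseline pressure). Device and procedure details the sources do not fully
#' specify (the semirigid scope's working channel and length, the three
#' irrigation pressures, the stone locations, the baseline pressure) enter
#' as documented defaults that can be overridden.
#'
#' @param rehman_sheaths sheath labels for the flexible-scope runs, `NA`
#'   meaning no sheath.
#' @param shao_scope the semirigid ureteroscope.
#' @param shao_pressures the three irrigation pressures in Pa.
#' @param shao_stone_locations stone distances from the ureteral orifice
#'   in m (distal, mid, proximal).
#' @param shao_baseline baseline renal pelvis pressure in Pa.
#' @return a list of 13 [scenario_config()] objects.
#' @export
validation_scenarios <- function(
    rehman_sheaths = c(NA, "10/12", "12/14", "14/16"),
    shao_scope = ureteroscope(french_to_meters(8), french_to_meters(5), 0.315,
                              label = "Wolf 8/9.8 Fr semirigid"),
    shao_pressures = cmH2O_to_Pa(c(200, 150, 100)),
    shao_stone_locations = c(0.05, 0.125, 0.25),
    shao_baseline = cmH2O_to_Pa(10)) {
  out <- list()
  for (sh in rehman_sheaths) {
    sheath <- if (is.na(sh)) NULL else sheath_from_label(sh)
    lbl <- sprintf("Rehman-style, %s",
                   if (is.na(sh)) "no sheath" else paste0(sh, " Fr"))
    out[[length(out) + 1]] <- scenario_config(
      lbl, sheath = sheath, irrigation_pressure = cmH2O_to_Pa(200))
  }
  loc_names <- c("distal", "mid", "proximal")[seq_along(shao_stone_locations)]
  for (i in seq_along(shao_stone_locations)) {
    for (p in shao_pressures) {
      lbl <- sprintf("Shao-style, %s stone, %.0f cmH2O", loc_names[i],
                     Pa_to_cmH2O(p))
      out[[length(out) + 1]] <- scenario_config(
        lbl, scope = shao_scope, irrigation_pressure = p,
        initial_pressure = shao_baseline,
        stone_location = shao_stone_locations[i])
    }
  }
  out
}

#' Nondimensional curve-collapse check
#'
#' Evaluates each scenario's inserted-phase solution (or its running time
#' average) on a shared nondimensional time grid, rescaling pressure by a
#' per-curve characteristic pressure and time by the per-curve rise time.
#' With `normalization = "p_max"`, every zero-baseline scenario reduces to
#' \eqn{1 - e^{-\hat t}} exactly, so the curves collapse to machine
#' precision; nonzero baseline pressures leave a small residual. With
#' `normalization = "p_irr"` the curves group by resistance ratio instead.
#'
#' @param scenarios list of [scenario_config()] (at least two).
#' @param normalization `"p_max"` (per-curve plateau) or `"p_irr"`
#'   (per-curve irrigation pressure).
#' @param what `"instantaneous"` pressure or `"running_mean"`.
#' @param t_hat nondimensional time grid (positive, increasing).
#' @param group_tol curves whose maximum pointwise distance is below this
#'   are counted as one group.
#' @return an object of class `collapse_report`: fields `curves` (matrix,
#'   one column per scenario), `t_hat`, `dispersion` (max pairwise pointwise
#'   deviation), `n_groups`, `labels`.
#' @export
collapse_check <- function(scenarios, normalization = c("p_max", "p_irr"),
                           what = c("instantaneous", "running_mean"),
                           t_hat = seq(0.025, 5, length.out = 200),
                           group_tol = 1e-9) {
  if (length(scenarios) < 2) stop("need at least two scenarios", call. = FALSE)
  normalization <- match.arg(normalization)
  what <- match.arg(what)
  if (any(t_hat <= 0) || any(diff(t_hat) <= 0)) {
    stop("t_hat must be positive and increasing", call. = FALSE)
  }
  curves <- sapply(scenarios, function(sc) {
    params <- scenario_parameters(sc)
    tau <- rise_time(params)
    scale <- switch(normalization,
                    p_max = steady_state_pressure(params),
                    p_irr = params$irrigation_pressure)
    f <- switch(what, instantaneous = insertion_pressure,
                running_mean = running_mean_pressure)
    f(t_hat * tau, params) / scale
  })
  labels <- vapply(scenarios, `[[`, "", "label")
  colnames(curves) <- labels
  d <- as.matrix(stats::dist(t(curves), method = "maximum"))
  groups <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"),
                          h = group_tol)
  structure(list(curves = curves, t_hat = t_hat,
                 dispersion = max(d), n_groups = max(groups),
                 groups = groups, labels = labels),
            class = "collapse_report")
}

#' @export
print.collapse_report <- function(x, ...) {
  cat(sprintf("<collapse_report> %d curves, %d groups, dispersion %.3e\n",
              ncol(x$curves), x$n_groups, x$dispersion))
  invisible(x)
}
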