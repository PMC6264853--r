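#' Circuit parameters for the pressure dynamics
#'
#' Collects everything the first-order compliance model needs: the three
#' hydraulic resistances, the renal pelvis stiffness K, the irrigation
#' pressure and the initial gauge pressure. The governing equation while the
#' scope is inserted is
#' \deqn{dP/dt + (K/R_{in})(1 + R_{in}/R_{out}) P = (K/R_{in}) P_{irr},}
#' and after withdrawal \eqn{dP/dt + (K/R_w) P = 0}.
#'
#' @param resistances a [resistance_set()].
#' @param stiffness renal pelvis stiffness K in Pa/m^3; > 0.
#' @param irrigation_pressure irrigation gauge pressure in Pa; > 0.
#' @param initial_pressure initial gauge pressure in Pa; >= 0.
#' @return an object of class `circuit_parameters`.
#' @export
circuit_parameters <- function(resistances, stiffness, irrigation_pressure,
                               initial_pressure = 0) {
  stopifnot(inherits(resistances, "resistance_set"))
  .check_positive(stiffness = stiffness,
                  irrigation_pressure = irrigation_pressure)
  if (!is.numeric(initial_pressure) || length(initial_pressure) != 1 ||
      !is.finite(initial_pressure) || initial_pressure < 0) {
    stop("initial_pressure must be a single non-negative number", call. = FALSE)
  }
  structure(list(resistances = resistances, stiffness = stiffness,
                 irrigation_pressure = irrigation_pressure,
                 initial_pressure = initial_pressure),
            class = "circuit_parameters")
}

#' @export
print.circuit_parameters <- function(x, ...) {
  cat(sprintf(paste0("<circuit_parameters> P_irr %.1f cmH2O, P_0 %.1f cmH2O, ",
                     "K %.2f cmH2O/mL\n"),
              Pa_to_cmH2O(x$irrigation_pressure),
              Pa_to_cmH2O(x$initial_pressure),
              x$stiffness * 1e-6 / 98.1))
  print(x$resistances)
  cat(sprintf("  plateau %.1f%% of P_irr, tau_in %.2f min, tau_out %.2f min\n",
              100 * steady_state_pressure(x) / x$irrigation_pressure,
              rise_time(x) / 60, decay_time(x) / 60))
  invisible(x)
}

#' Plateau pressure, rise time and decay time
#'
#' With the scope inserted the pressure relaxes exponentially toward the
#' plateau \eqn{P_{max} = P_{irr} (1 + R_{in}/R_{out})^{-1}} with time
#' constant \eqn{\tau_{in} = (R_{in}/K)(1 + R_{in}/R_{out})^{-1}}; after
#' withdrawal it decays to baseline with \eqn{\tau_{out} = R_w / K}. The
#' plateau is always strictly below the irrigation pressure and is set by
#' the resistance ratio alone; the stiffness only sets the timescales.
#'
#' @param params a [circuit_parameters()].
#' @return pressure in Pa (`steady_state_pressure`) or time in s.
#' @export
steady_state_pressure <- function(params) {
  stopifnot(inherits(params, "circuit_parameters"))
  r <- params$resistances
  params$irrigation_pressure / (1 + r$inflow / r$outflow)
}

#' @rdname steady_state_pressure
#' @export
rise_time <- function(params) {
  stopifnot(inherits(params, "circuit_parameters"))
  r <- params$resistances
  (r$inflow / params$stiffness) / (1 + r$inflow / r$outflow)
}

#' @rdname steady_state_pressure
#' @export
decay_time <- function(params) {
  stopifnot(inherits(params, "circuit_parameters"))
  params$resistances$withdrawal / params$stiffness
}

#' Closed-form pressure solutions
#'
#' `insertion_pressure()` evaluates the inserted-phase solution
#' \eqn{P(t) = P_{max}(1 - e^{-t/\tau_{in}}) + P_0 e^{-t/\tau_{in}}};
#' `withdrawal_pressure()` the post-removal decay
#' \eqn{P(t) = P_r e^{-(t - t_r)/\tau_{out}}};
#' `running_mean_pressure()` the exact running time average of the inserted
#' solution,
#' \eqn{\bar P(t) = P_{max} - (\tau_{in}/t)(P_{max} - P_0)(1 - e^{-t/\tau_{in}})}.
#'
#' @param t time in s (vectorised); `insertion_pressure` requires `t >= 0`,
#'   `running_mean_pressure` requires `t > 0`.
#' @param params a [circuit_parameters()].
#' @return gauge pressure in Pa.
#' @export
insertion_pressure <- function(t, params) {
  stopifnot(inherits(params, "circuit_parameters"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be finite and non-negative", call. = FALSE)
  }
  p_max <- steady_state_pressure(params)
  tau <- rise_time(params)
  e <- exp(-t / tau)
  p_max * (1 - e) + params$initial_pressure * e
}

#' @rdname insertion_pressure
#' @param t_r time of scope removal in s.
#' @param p_r gauge pressure at removal in Pa; >= 0.
#' @param tau_out decay time constant in s; > 0.
#' @export
withdrawal_pressure <- function(t, t_r, p_r, tau_out) {
  .check_positive(tau_out = tau_out)
  if (!is.numeric(p_r) || p_r < 0) stop("p_r must be >= 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < t_r)) {
    stop("t must be finite and >= t_r", call. = FALSE)
  }
  p_r * exp(-(t - t_r) / tau_out)
}

#' @rdname insertion_pressure
#' @export
running_mean_pressure <- function(t, params) {
  stopifnot(inherits(params, "circuit_parameters"))
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("t must be finite and positive", call. = FALSE)
  }
  p_max <- steady_state_pressure(params)
  tau <- rise_time(params)
  x <- t / tau
  # -expm1(-x)/x is the numerically stable form of (1 - e^-x)/x near x = 0
  p_max - (p_max - params$initial_pressure) * (-expm1(-x) / x)
}

#' Sampled pressure-versus-time trace
#'
#' @param times strictly increasing sample times in s.
#' @param pressures gauge pressures in Pa, same length as `times`.
#' @param phase per-sample phase label, `"inserted"` or `"withdrawn"`
#'   (recycled if scalar).
#' @return an object of class `pressure_trace`; `as.data.frame()` gives
#'   columns `time`, `pressure`, `phase` in SI.
#' @export
pressure_trace <- function(times, pressures, phase = "inserted") {
  if (length(times) != length(pressures) || length(times) == 0) {
    stop("times and pressures must be nonempty and of equal length",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(pressures)) || any(pressures < 0)) {
    stop("pressures must be finite and non-negative", call. = FALSE)
  }
  phase <- rep_len(as.character(phase), length(times))
  if (!all(phase %in% c("inserted", "withdrawn"))) {
    stop("phase labels must be 'inserted' or 'withdrawn'", call. = FALSE)
  }
  structure(list(times = as.numeric(times), pressures = as.numeric(pressures),
                 phase = phase),
            class = "pressure_trace")
}

#' @export
as.data.frame.pressure_trace <- function(x, ...) {
  data.frame(time = x$times, pressure = x$pressures, phase = x$phase)
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %d samples over %.1f min, peak %.1f cmH2O\n",
              length(x$times), diff(range(x$times)) / 60,
              Pa_to_cmH2O(max(x$pressures))))
  invisible(x)
}

#' @export
plot.pressure_trace <- function(x, xlab = "time [min]",
                                ylab = "renal pelvis pressure [cm H2O]", ...) {
  graphics::plot(x$times / 60, Pa_to_cmH2O(x$pressures), type = "l",
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Numerically integrate the governing pressure ODE
#'
#' Integrates the stated linear first-order equation for one phase with
#' `deSolve::ode` (lsoda). This is the numerical oracle the closed-form
#' solutions are verified against; it is not used by the simulator itself.
#'
#' @param params a [circuit_parameters()].
#' @param phase `"inserted"` (source term present, resistances Rin/Rout) or
#'   `"withdrawn"` (free decay through Rw).
#' @param t_span nondecreasing vector of output times in s.
#' @param initial_pressure starting gauge pressure in Pa; defaults to the
#'   parameter set's `initial_pressure`.
#' @param rtol,atol relative and absolute step-control tolerances.
#' @return a [pressure_trace()].
#' @export
integrate_ode <- function(params, phase = c("inserted", "withdrawn"),
                          t_span, initial_pressure = params$initial_pressure,
                          rtol = 1e-9, atol = 1e-6) {
  stopifnot(inherits(params, "circuit_parameters"))
  phase <- match.arg(phase)
  if (any(diff(t_span) < 0)) stop("t_span must be nondecreasing", call. = FALSE)
  r <- params$resistances
  k <- params$stiffness
  rhs <- if (phase == "inserted") {
    function(t, y, p) {
      q_in <- (params$irrigation_pressure - y[1]) / r$inflow
      q_out <- y[1] / r$outflow
      list(k * (q_in - q_out))
    }
  } else {
    function(t, y, p) list(-k * y[1] / r$withdrawal)
  }
  sol <- deSolve::ode(y = c(P = initial_pressure), times = t_span, func = rhs,
                      parms = NULL, rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    stop("ODE step control failed: istate = ", attr(sol, "istate")[1],
         call. = FALSE)
  }
  pressure_trace(sol[, "time"], pmax(sol[, "P"], 0), phase)
}

#' Nondimensionalize a pressure trace
#'
#' Divides pressures and times pointwise by characteristic scales (for
#' example the irrigation pressure or plateau pressure, and the rise time).
#' Traces sharing a resistance ratio collapse onto a single curve in these
#' variables; with zero initial pressure every inserted-phase trace becomes
#' \eqn{1 - e^{-\hat t}} when scaled by its own plateau and rise time.
#'
#' @param trace a [pressure_trace()].
#' @param scale_pressure,scale_time positive characteristic scales.
#' @return a `pressure_trace` in dimensionless variables (no resampling).
#' @export
nondimensionalize <- function(trace, scale_pressure, scale_time) {
  stopifnot(inherits(trace, "pressure_trace"))
  .check_positive(scale_pressure = scale_pressure, scale_time = scale_time)
  pressure_trace(trace$times / scale_time, trace$pressures / scale_pressure,
                 trace$phase)
}

#' Export a trace as delimited text
#'
#' Writes a CSV with mandatory header `time_s,pressure_cmH2O,phase`; units
#' are embedded in the column names to prevent silent unit drift.
#'
#' @param trace a [pressure_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  df <- data.frame(time_s = trace$times,
                   pressure_cmH2O = Pa_to_cmH2O(trace$pressures),
                   phase = trace$phase)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
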