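#' Surgical phases and protocols
#'
#' A protocol is an ordered list of phases, each either `"inserted"` (scope
#' in the renal pelvis, irrigation running) or `"withdrawn"` (scope out,
#' irrigation off, pressure draining through the relaxed tract). Protocols
#' begin and end with an inserted phase and withdrawals are never adjacent,
#' so the number of withdrawals is one less than the number of insertions.
#'
#' @param kind `"inserted"` or `"withdrawn"`.
#' @param duration phase duration in s; > 0.
#' @return `phase()`: an object of class `surgical_phase`.
#' @export
phase <- function(kind = c("inserted", "withdrawn"), duration) {
  kind <- match.arg(kind)
  .check_positive(duration = duration)
  structure(list(kind = kind, duration = duration), class = "surgical_phase")
}

#' @rdname phase
#' @param phases list of `surgical_phase` objects.
#' @param name protocol label.
#' @return `protocol()`: an object of class `surgical_protocol`.
#' @export
protocol <- function(phases, name = "protocol") {
  if (length(phases) == 0 || !all(vapply(phases, inherits, TRUE, "surgical_phase"))) {
    stop("phases must be a nonempty list of phase() objects", call. = FALSE)
  }
  kinds <- vapply(phases, `[[`, "", "kind")
  if (kinds[1] != "inserted" || kinds[length(kinds)] != "inserted") {
    stop("a protocol must begin and end with an inserted phase", call. = FALSE)
  }
  if (any(kinds[-1] == "withdrawn" & kinds[-length(kinds)] == "withdrawn")) {
    stop("withdrawn phases must not be adjacent", call. = FALSE)
  }
  structure(list(phases = phases, name = name), class = "surgical_protocol")
}

#' @rdname phase
#' @param n_insertions number of equal insertion intervals.
#' @param insertion_min,withdrawal_min interval durations in minutes.
#' @export
periodic_protocol <- function(n_insertions, insertion_min, withdrawal_min,
                              name = NULL) {
  if (n_insertions < 1) stop("need at least one insertion", call. = FALSE)
  if (is.null(name)) {
    name <- if (n_insertions == 1) {
      sprintf("%g min x 1 / no withdrawal", insertion_min)
    } else {
      sprintf("%g min x %d / %g min x %d", insertion_min, n_insertions,
              withdrawal_min, n_insertions - 1)
    }
  }
  phases <- list()
  for (k in seq_len(n_insertions)) {
    phases <- c(phases, list(phase("inserted", insertion_min * 60)))
    if (k < n_insertions) {
      phases <- c(phases, list(phase("withdrawn", withdrawal_min * 60)))
    }
  }
  protocol(phases, name)
}

#' @rdname phase
#' @param x a `surgical_protocol`.
#' @export
total_time <- function(x) {
  stopifnot(inherits(x, "surgical_protocol"))
  sum(vapply(x$phases, `[[`, 0, "duration"))
}

#' @rdname phase
#' @export
insertion_time <- function(x) {
  stopifnot(inherits(x, "surgical_protocol"))
  sum(vapply(x$phases, function(p) if (p$kind == "inserted") p$duration else 0, 0))
}

#' @export
print.surgical_protocol <- function(x, ...) {
  cat(sprintf("<surgical_protocol> %s: %d phases, %g min total (%g min inserted)\n",
              x$name, length(x$phases), total_time(x) / 60,
              insertion_time(x) / 60))
  invisible(x)
}

#' The four reference withdrawal strategies
#'
#' Every option accumulates the same 20 minutes of scope-inserted time but
#' differs in withdrawal pattern: no withdrawal (20 min total); two 10-min
#' insertions with one 5-min withdrawal (25 min); five 4-min insertions with
#' four 2-min withdrawals (28 min); ten 2-min insertions with nine 1-min
#' withdrawals (29 min).
#'
#' @return a named list of four [protocol()] objects
#'   (`option1` ... `option4`).
#' @export
reference_protocols <- function() {
  list(option1 = periodic_protocol(1, 20, 0),
       option2 = periodic_protocol(2, 10, 5),
       option3 = periodic_protocol(5, 4, 2),
       option4 = periodic_protocol(10, 2, 1))
}

# Exact per-phase chaining of the closed-form solutions. Each row of the
# returned data frame carries the analytic start/end pressures and the exact
# time integral of the pressure over the phase, so averaged metrics do not
# depend on the sampling grid.
.protocol_segments <- function(prot, params) {
  p_max <- steady_state_pressure(params)
  tau_in <- rise_time(params)
  tau_out <- decay_time(params)
  p <- params$initial_pressure
  t0 <- 0
  rows <- lapply(prot$phases, function(ph) NULL)
  for (i in seq_along(prot$phases)) {
    ph <- prot$phases[[i]]
    if (ph$kind == "inserted") {
      e <- exp(-ph$duration / tau_in)
      p_end <- p_max + (p - p_max) * e
      integral <- p_max * ph$duration - tau_in * (p_max - p) * (1 - e)
    } else {
      e <- exp(-ph$duration / tau_out)
      p_end <- p * e
      integral <- p * tau_out * (1 - e)
    }
    rows[[i]] <- data.frame(kind = ph$kind, t_start = t0,
                            duration = ph$duration, p_start = p,
                            p_end = p_end, integral = integral)
    t0 <- t0 + ph$duration
    p <- p_end
  }
  do.call(rbind, rows)
}

#' Simulate an insertion/withdrawal protocol
#'
#' Chains the closed-form phase solutions: each inserted phase follows the
#' exponential rise toward the plateau from the pressure it inherits, each
#' withdrawn phase decays exponentially through the relaxed tract, and the
#' pressure is continuous at every phase boundary (reinsertion is treated as
#' instantaneous). The returned trace carries the exact per-phase integrals
#' as an attribute, so [time_averaged_pressure()] is independent of the
#' sampling interval.
#'
#' @param prot a [protocol()].
#' @param params a [circuit_parameters()].
#' @param dt sampling interval for the returned trace, in s.
#' @return a [pressure_trace()] with attribute `"segments"`.
#' @export
simulate_protocol <- function(prot, params, dt = 1) {
  stopifnot(inherits(prot, "surgical_protocol"),
            inherits(params, "circuit_parameters"))
  .check_positive(dt = dt)
  seg <- .protocol_segments(prot, params)
  tau_in <- rise_time(params)
  tau_out <- decay_time(params)
  p_max <- steady_state_pressure(params)
  times <- numeric(0); pressures <- numeric(0); labels <- character(0)
  for (i in seq_len(nrow(seg))) {
    # sample [t_start, t_start + duration); the final phase closes the interval
    tloc <- seq(0, seg$duration[i], by = dt)
    if (tloc[length(tloc)] < seg$duration[i] && i == nrow(seg)) {
      tloc <- c(tloc, seg$duration[i])
    }
    if (i > 1) tloc <- tloc[-1]  # boundary sample belongs to the previous phase
    pl <- if (seg$kind[i] == "inserted") {
      p_max + (seg$p_start[i] - p_max) * exp(-(if (i > 1) tloc else tloc) / tau_in)
    } else {
      seg$p_start[i] * exp(-tloc / tau_out)
    }
    times <- c(times, seg$t_start[i] + tloc)
    pressures <- c(pressures, pl)
    labels <- c(labels, rep(seg$kind[i], length(tloc)))
  }
  out <- pressure_trace(times, pmax(pressures, 0), labels)
  attr(out, "segments") <- seg
  attr(out, "params") <- params
  out
}

#' Time-averaged pressure of a simulated protocol
#'
#' Computed from the exact per-phase integrals attached by
#' [simulate_protocol()], not from grid quadrature: refining the sampling
#' interval leaves the result bit-identical. The averaging window is either
#' the whole procedure (insertions plus withdrawals) or the cumulative
#' inserted time only.
#'
#' @param trace a trace returned by [simulate_protocol()].
#' @param window `"full"` (whole timeline) or `"insertion"` (inserted
#'   phases only).
#' @return mean gauge pressure in Pa.
#' @export
time_averaged_pressure <- function(trace, window = c("full", "insertion")) {
  stopifnot(inherits(trace, "pressure_trace"))
  window <- match.arg(window)
  seg <- attr(trace, "segments")
  if (is.null(seg)) {
    stop("trace carries no exact segment data; use simulate_protocol()",
         call. = FALSE)
  }
  if (window == "insertion") seg <- seg[seg$kind == "inserted", , drop = FALSE]
  if (nrow(seg) == 0 || sum(seg$duration) <= 0) {
    stop("empty averaging window", call. = FALSE)
  }
  sum(seg$integral) / sum(seg$duration)
}

#' @describeIn time_averaged_pressure peak pressure over the trace, taken
#'   from the exact phase-boundary pressures (the maximum of any phase is
#'   attained at one of its endpoints for this model).
#' @export
peak_pressure <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  seg <- attr(trace, "segments")
  if (is.null(seg)) return(max(trace$pressures))
  max(seg$p_start, seg$p_end)
}

#' Summarise a withdrawal strategy
#'
#' @param prot a [protocol()].
#' @param params a [circuit_parameters()].
#' @param window averaging window, see [time_averaged_pressure()].
#' @return an object of class `strategy_result` with fields
#'   `time_averaged_pressure`, `peak_pressure`, `total_procedure_time`,
#'   `cumulative_insertion_time` (SI units).
#' @export
evaluate_protocol <- function(prot, params, window = "full") {
  trace <- simulate_protocol(prot, params, dt = 5)
  structure(list(name = prot$name,
                 time_averaged_pressure = time_averaged_pressure(trace, window),
                 peak_pressure = peak_pressure(trace),
                 total_procedure_time = total_time(prot),
                 cumulative_insertion_time = insertion_time(prot)),
            class = "strategy_result")
}

#' Relative decrease of the time-averaged pressure versus a baseline
#'
#' @param option,baseline [evaluate_protocol()] results; the baseline is
#'   conventionally the no-withdrawal strategy, whose time-averaged pressure
#'   is never exceeded by any withdrawal strategy.
#' @return dimensionless fraction `(baseline - option) / baseline`.
#' @export
relative_decrease <- function(option, baseline) {
  stopifnot(inherits(option, "strategy_result"),
            inherits(baseline, "strategy_result"))
  if (baseline$time_averaged_pressure <= 0) {
    stop("baseline time-averaged pressure must be positive", call. = FALSE)
  }
  (baseline$time_averaged_pressure - option$time_averaged_pressure) /
    baseline$time_averaged_pressure
}

#' Sweep withdrawal strategies across sheath sizes
#'
#' Evaluates every (sheath, protocol) combination for a fixed scope, anatomy
#' and irrigation pressure; within each sheath, relative decreases are taken
#' against the first protocol in the list (the no-withdrawal baseline for
#' the reference set).
#'
#' @param sheaths list of [access_sheath()] objects (or labels accepted by
#'   [sheath_from_label()]).
#' @param protocols list of [protocol()] objects, baseline first.
#' @param scope a [ureteroscope()].
#' @param anat an [anatomy()].
#' @param irrigation_pressure irrigation pressure in Pa.
#' @param fluid a [fluid_properties()].
#' @param window averaging window, see [time_averaged_pressure()].
#' @return a data frame with one row per (sheath, protocol): columns
#'   `sheath_label`, `protocol_name`, `mean_pressure_cmH2O`,
#'   `peak_pressure_cmH2O`, `relative_decrease_pct`, `total_time_min`.
#' @export
strategy_sweep <- function(sheaths, protocols,
                           scope = default_ureteroscope(),
                           anat = default_anatomy(),
                           irrigation_pressure = cmH2O_to_Pa(150),
                           fluid = fluid_properties(),
                           window = "full") {
  if (length(sheaths) == 0 || length(protocols) == 0) {
    stop("sheaths and protocols must be nonempty", call. = FALSE)
  }
  sheaths <- lapply(sheaths, function(s) {
    if (inherits(s, "access_sheath")) s else sheath_from_label(s)
  })
  rows <- list()
  for (sh in sheaths) {
    res <- compute_resistances(scope, anat, sh, fluid)
    params <- circuit_parameters(res, anat$stiffness, irrigation_pressure)
    results <- lapply(protocols, evaluate_protocol, params = params,
                      window = window)
    baseline <- results[[1]]
    for (r in results) {
      rows[[length(rows) + 1]] <- data.frame(
        sheath_label = sh$label,
        protocol_name = r$name,
        mean_pressure_cmH2O = Pa_to_cmH2O(r$time_averaged_pressure),
        peak_pressure_cmH2O = Pa_to_cmH2O(r$peak_pressure),
        relative_decrease_pct = 100 * relative_decrease(r, baseline),
        total_time_min = r$total_procedure_time / 60)
    }
  }
  do.call(rbind, rows)
}
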