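#' Circuit parameters implied by a run configuration
#'
#' @param config a `run_config` from [load_config()].
#' @return a [circuit_parameters()].
#' @export
config_parameters <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sc <- scenario_config(config$label, scope = config$scope,
                        anat = config$anat, sheath = config$sheath,
                        irrigation_pressure = config$irrigation_pressure,
                        initial_pressure = config$initial_pressure,
                        stone_location = config$stone_location)
  scenario_parameters(sc, config$fluid)
}

# Exact time spent above a pressure threshold, summed over the analytic
# phase segments: every phase is a monotone exponential toward a known
# asymptote, so each crossing time has a closed form.
.segment_time_above <- function(p0, asymptote, tau, duration, threshold) {
  if (p0 >= threshold && asymptote >= threshold) return(duration)
  if (p0 <= threshold && asymptote <= threshold) {
    # touches the threshold at most at an endpoint: measure-zero
    return(0)
  }
  t_cross <- tau * log((p0 - asymptote) / (threshold - asymptote))
  if (p0 > threshold) min(t_cross, duration)          # falls through threshold
  else max(duration - t_cross, 0)                     # rises through threshold
}

#' Time spent above a pressure threshold
#'
#' Clinically, the risk of pyelovenous backflow rises with the time the
#' renal pelvis pressure stays above roughly 40 cm H2O. Computed exactly
#' from the analytic phase segments attached by [simulate_protocol()].
#'
#' @param trace a trace from [simulate_protocol()].
#' @param params the [circuit_parameters()] used to simulate it.
#' @param threshold pressure threshold in Pa.
#' @return time above threshold in s.
#' @export
time_above_threshold <- function(trace, params, threshold = cmH2O_to_Pa(40)) {
  stopifnot(inherits(trace, "pressure_trace"),
            inherits(params, "circuit_parameters"))
  seg <- attr(trace, "segments")
  if (is.null(seg)) stop("trace carries no segment data", call. = FALSE)
  tau_in <- rise_time(params)
  tau_out <- decay_time(params)
  p_max <- steady_state_pressure(params)
  total <- 0
  for (i in seq_len(nrow(seg))) {
    if (seg$kind[i] == "inserted") {
      total <- total + .segment_time_above(seg$p_start[i], p_max, tau_in,
                                           seg$duration[i], threshold)
    } else {
      total <- total + .segment_time_above(seg$p_start[i], 0, tau_out,
                                           seg$duration[i], threshold)
    }
  }
  total
}

#' Run a configured simulation
#'
#' Builds the hydraulic circuit from the configuration, simulates the
#' configured protocol and summarises the run (plateau pressure, time
#' constants, peak and time-averaged pressures, time above the backflow
#' threshold). Optionally writes the trace CSV, a YAML summary and a plot,
#' and logs all effective parameters.
#'
#' @param config a `run_config` from [load_config()].
#' @param out_dir directory for output artifacts, or `NULL` to skip writing.
#' @param plot also write a PDF plot of the trace (requires `out_dir`).
#' @param quiet suppress the parameter log.
#' @return an object of class `uroflow_run`: fields `config`, `params`,
#'   `trace` and `summary` (a data frame in clinical units).
#' @export
run_simulation <- function(config, out_dir = NULL, plot = FALSE,
                           quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  params <- config_parameters(config)
  trace <- simulate_protocol(config$protocol, params,
                             dt = config$sampling_interval)
  summary <- data.frame(
    label = config$label,
    plateau_cmH2O = Pa_to_cmH2O(steady_state_pressure(params)),
    tau_in_min = rise_time(params) / 60,
    tau_out_min = decay_time(params) / 60,
    peak_cmH2O = Pa_to_cmH2O(peak_pressure(trace)),
    mean_cmH2O = Pa_to_cmH2O(time_averaged_pressure(trace)),
    time_above_threshold_min =
      time_above_threshold(trace, params, config$threshold) / 60,
    threshold_cmH2O = Pa_to_cmH2O(config$threshold),
    total_time_min = total_time(config$protocol) / 60)
  if (!quiet) {
    message(sprintf("run '%s': Rin=%.3e Rout=%.3e Rw=%.3e Pa.s/m^3",
                    config$label, params$resistances$inflow,
                    params$resistances$outflow, params$resistances$withdrawal))
    message(sprintf("  P_irr=%.1f cmH2O (%.0f Pa), K=%.2f cmH2O/mL (%.3e Pa/m^3)",
                    Pa_to_cmH2O(config$irrigation_pressure),
                    config$irrigation_pressure,
                    config$anat$stiffness * 1e-6 / 98.1, config$anat$stiffness))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    slug <- gsub("[^A-Za-z0-9]+", "_", config$label)
    write_trace_csv(trace, file.path(out_dir, paste0(slug, "_trace.csv")))
    yaml::write_yaml(as.list(summary), file.path(out_dir, paste0(slug, "_summary.yaml")))
    if (plot) {
      grDevices::pdf(file.path(out_dir, paste0(slug, ".pdf")), width = 6, height = 4)
      plot(trace, main = config$label)
      grDevices::dev.off()
    }
  }
  structure(list(config = config, params = params, trace = trace,
                 summary = summary),
            class = "uroflow_run")
}

#' @export
print.uroflow_run <- function(x, ...) {
  cat(sprintf("<uroflow_run> %s\n", x$config$label))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the withdrawal-strategy sweep from a sweep specification
#'
#' @param path YAML file with keys `sheaths` (labels), `protocols` (names
#'   from [reference_protocols()]) and optional `irrigation: pressure`.
#' @param out CSV output path, or `NULL`.
#' @return the sweep data frame, invisibly when `out` is given.
#' @export
run_sweep <- function(path, out = NULL) {
  spec <- yaml::read_yaml(path)
  prots <- reference_protocols()[unlist(spec$protocols)]
  if (any(vapply(prots, is.null, TRUE))) {
    stop("unknown protocol name in sweep spec", call. = FALSE)
  }
  p_irr <- if (!is.null(spec$irrigation$pressure)) {
    parse_quantity(spec$irrigation$pressure, "pressure")
  } else cmH2O_to_Pa(150)
  tab <- strategy_sweep(as.list(unlist(spec$sheaths)), unname(prots),
                        irrigation_pressure = p_irr)
  if (!is.null(out)) {
    utils::write.csv(tab, out, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
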