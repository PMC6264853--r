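#' Load a simulation configuration
#'
#' Configurations are YAML files with nested sections mirroring the
#' parameter groups: `irrigation`, `ureteroscope`, `sheath` (optional),
#' `physiology`, `protocol` and `simulation`. Every dimensional field is a
#' string stating its unit (`"7.5 Fr"`, `"150 cmH2O"`, `"0.4 cmH2O/mL"`);
#' all quantities are converted to SI on load. Unknown keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param path path to a YAML configuration file.
#' @return an object of class `run_config` with fields `label`, `scope`,
#'   `sheath` (or `NULL`), `anat`, `fluid`, `irrigation_pressure`,
#'   `initial_pressure`, `stone_location`, `protocol`, `sampling_interval`,
#'   `threshold` (all SI).
#' @seealso [write_config()], [generate_fixtures()], [run_simulation()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  .build_config(raw, path)
}

.reject_unknown <- function(section, allowed, where) {
  extra <- setdiff(names(section), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
}

.require_keys <- function(section, keys, where) {
  missing <- setdiff(keys, names(section))
  if (length(missing)) {
    stop("missing key(s) in ", where, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

.build_config <- function(raw, path = "<config>") {
  .reject_unknown(raw, c("label", "irrigation", "ureteroscope", "sheath",
                         "physiology", "protocol", "simulation"), path)
  .require_keys(raw, c("irrigation", "ureteroscope", "physiology", "protocol"),
                path)

  irr <- raw$irrigation
  .reject_unknown(irr, c("pressure", "viscosity"), "irrigation")
  .require_keys(irr, "pressure", "irrigation")
  irrigation_pressure <- parse_quantity(irr$pressure, "pressure")
  fluid <- fluid_properties(
    if (is.null(irr$viscosity)) 1e-3 else parse_quantity(irr$viscosity, "viscosity"))

  us <- raw$ureteroscope
  .reject_unknown(us, c("label", "shaft_diameter", "channel_diameter",
                        "working_length"), "ureteroscope")
  .require_keys(us, c("shaft_diameter", "channel_diameter", "working_length"),
                "ureteroscope")
  scope <- ureteroscope(parse_quantity(us$shaft_diameter, "length"),
                        parse_quantity(us$channel_diameter, "length"),
                        parse_quantity(us$working_length, "length"),
                        label = if (is.null(us$label)) "ureteroscope" else us$label)

  sheath <- NULL
  if (!is.null(raw$sheath) && !identical(raw$sheath, "none")) {
    sh <- raw$sheath
    .reject_unknown(sh, c("label", "inner_diameter", "length"), "sheath")
    len <- if (is.null(sh$length)) 0.35 else parse_quantity(sh$length, "length")
    sheath <- if (!is.null(sh$inner_diameter)) {
      access_sheath(parse_quantity(sh$inner_diameter, "length"), len,
                    label = sh$label)
    } else if (!is.null(sh$label)) {
      sheath_from_label(sh$label, len)
    } else {
      stop("sheath section needs 'label' or 'inner_diameter'", call. = FALSE)
    }
    if (sheath$inner_diameter <= scope$shaft_diameter) {
      stop("sheath lumen must exceed the scope shaft diameter", call. = FALSE)
    }
  }

  ph <- raw$physiology
  .reject_unknown(ph, c("upj_diameter", "upj_length", "ureter_diameter",
                        "ureter_length", "upj_stretch", "ureter_stretch",
                        "stiffness", "initial_pressure", "stone_location"),
                  "physiology")
  defaults <- default_anatomy()
  getq <- function(key, dim, default) {
    if (is.null(ph[[key]])) default else parse_quantity(ph[[key]], dim)
  }
  anat <- anatomy(
    upj_diameter = getq("upj_diameter", "length", defaults$upj_diameter),
    upj_length = getq("upj_length", "length", defaults$upj_length),
    ureter_diameter = getq("ureter_diameter", "length", defaults$ureter_diameter),
    ureter_length = getq("ureter_length", "length", defaults$ureter_length),
    upj_stretch = if (is.null(ph$upj_stretch)) defaults$upj_stretch
                  else as.numeric(ph$upj_stretch),
    ureter_stretch = if (is.null(ph$ureter_stretch)) defaults$ureter_stretch
                     else as.numeric(ph$ureter_stretch),
    stiffness = getq("stiffness", "stiffness", defaults$stiffness))
  initial_pressure <- getq("initial_pressure", "pressure", 0)
  stone_location <- if (is.null(ph$stone_location)) NULL else
    parse_quantity(ph$stone_location, "length")

  prot <- .parse_protocol(raw$protocol)

  sim <- if (is.null(raw$simulation)) list() else raw$simulation
  .reject_unknown(sim, c("sampling_interval", "threshold"), "simulation")
  sampling_interval <- if (is.null(sim$sampling_interval)) 1 else
    parse_quantity(sim$sampling_interval, "time")
  threshold <- if (is.null(sim$threshold)) cmH2O_to_Pa(40) else
    parse_quantity(sim$threshold, "pressure")
  .check_positive(sampling_interval = sampling_interval)

  structure(list(label = if (is.null(raw$label)) "run" else raw$label,
                 scope = scope, sheath = sheath, anat = anat, fluid = fluid,
                 irrigation_pressure = irrigation_pressure,
                 initial_pressure = initial_pressure,
                 stone_location = stone_location,
                 protocol = prot,
                 sampling_interval = sampling_interval,
                 threshold = threshold),
            class = "run_config")
}

.parse_protocol <- function(p) {
  if (is.character(p) && length(p) == 1) {
    named <- reference_protocols()
    if (!p %in% names(named)) {
      stop("unknown protocol name '", p, "'; known: ",
           paste(names(named), collapse = ", "), call. = FALSE)
    }
    return(named[[p]])
  }
  if (is.list(p) && !is.null(p$name)) return(.parse_protocol(p$name))
  if (!is.list(p) || length(p) == 0) {
    stop("protocol must be a named option or a list of (kind, duration) pairs",
         call. = FALSE)
  }
  phases <- lapply(p, function(entry) {
    if (is.list(entry) && !is.null(entry$kind)) {
      phase(entry$kind, parse_quantity(entry$duration, "time"))
    } else if (length(entry) == 2) {
      phase(as.character(entry[[1]]), parse_quantity(entry[[2]], "time"))
    } else {
      stop("cannot parse protocol entry", call. = FALSE)
    }
  })
  protocol(phases, name = "custom")
}

.fmt_si <- function(x, unit) sprintf("%.17g %s", x, unit)

#' Write a configuration back to YAML
#'
#' Emits all quantities in SI units with full precision, so that
#' `load_config(write_config(cfg, path))` reproduces the configuration
#' exactly.
#'
#' @param config a `run_config` (from [load_config()] or [scenario_to_config()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  an <- config$anat
  out <- list(
    label = config$label,
    irrigation = list(pressure = .fmt_si(config$irrigation_pressure, "Pa"),
                      viscosity = .fmt_si(config$fluid$viscosity, "Pa.s")),
    ureteroscope = list(label = config$scope$label,
                        shaft_diameter = .fmt_si(config$scope$shaft_diameter, "m"),
                        channel_diameter = .fmt_si(config$scope$channel_diameter, "m"),
                        working_length = .fmt_si(config$scope$working_length, "m")),
    physiology = list(upj_diameter = .fmt_si(an$upj_diameter, "m"),
                      upj_length = .fmt_si(an$upj_length, "m"),
                      ureter_diameter = .fmt_si(an$ureter_diameter, "m"),
                      ureter_length = .fmt_si(an$ureter_length, "m"),
                      upj_stretch = an$upj_stretch,
                      ureter_stretch = an$ureter_stretch,
                      stiffness = .fmt_si(an$stiffness, "Pa/m3"),
                      initial_pressure = .fmt_si(config$initial_pressure, "Pa")),
    protocol = lapply(config$protocol$phases, function(p) {
      list(kind = p$kind, duration = .fmt_si(p$duration, "s"))
    }),
    simulation = list(sampling_interval = .fmt_si(config$sampling_interval, "s"),
                      threshold = .fmt_si(config$threshold, "Pa")))
  if (!is.null(config$sheath)) {
    out$sheath <- list(label = config$sheath$label,
                       inner_diameter = .fmt_si(config$sheath$inner_diameter, "m"),
                       length = .fmt_si(config$sheath$length, "m"))
  }
  if (!is.null(config$stone_location)) {
    out$physiology$stone_location <- .fmt_si(config$stone_location, "m")
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Turn a scenario into a runnable configuration
#'
#' @param scenario a [scenario_config()].
#' @param prot the protocol to attach (a single 20-minute insertion by
#'   default, matching the reference no-withdrawal strategy).
#' @param fluid a [fluid_properties()].
#' @return a `run_config`.
#' @export
scenario_to_config <- function(scenario, prot = reference_protocols()$option1,
                               fluid = fluid_properties()) {
  stopifnot(inherits(scenario, "scenario_config"))
  structure(list(label = scenario$label, scope = scenario$scope,
                 sheath = scenario$sheath, anat = scenario$anat, fluid = fluid,
                 irrigation_pressure = scenario$irrigation_pressure,
                 initial_pressure = scenario$initial_pressure,
                 stone_location = scenario$stone_location,
                 protocol = prot, sampling_interval = 1,
                 threshold = cmH2O_to_Pa(40)),
            class = "run_config")
}

#' Emit the bundled scenario configurations
#'
#' Writes runnable YAML configurations for the eight-curve sheath
#' comparison, the thirteen validation scenarios, the four reference
#' withdrawal protocols (with a 10/12 Fr sheath at 150 cm H2O) and a sweep
#' specification, so every bundled result can be reproduced by replaying a
#' generated file.
#'
#' @param dir target directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
generate_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(config, name) {
    p <- file.path(dir, name)
    write_config(config, p)
    paths <<- c(paths, p)
  }
  comparison <- sheath_comparison_scenarios()
  for (i in seq_along(comparison)) {
    emit(scenario_to_config(comparison[[i]]),
         sprintf("sheath_comparison_%02d.yaml", i))
  }
  validation <- validation_scenarios()
  for (i in seq_along(validation)) {
    emit(scenario_to_config(validation[[i]]),
         sprintf("validation_%02d.yaml", i))
  }
  prots <- reference_protocols()
  for (nm in names(prots)) {
    sc <- scenario_config(paste0("10/12 Fr, 150 cmH2O, ", prots[[nm]]$name),
                          sheath = sheath_from_label("10/12"))
    emit(scenario_to_config(sc, prot = prots[[nm]]),
         sprintf("protocol_%s.yaml", nm))
  }
  sweep <- list(label = "withdrawal strategy sweep",
                sheaths = c("10/12", "11/13", "12/14"),
                protocols = names(prots),
                irrigation = list(pressure = "150 cmH2O"))
  p <- file.path(dir, "strategy_sweep.yaml")
  yaml::write_yaml(sweep, p)
  paths <- c(paths, p)
  invisible(paths)
}
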