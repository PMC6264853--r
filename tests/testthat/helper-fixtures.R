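# Shared builders for the representative configuration: benchmark flexible
# scope (7.5 Fr shaft, 3.6 Fr channel, 67 cm), representative anatomy
# (UPJ 1.3 Fr x 0.5 cm, ureter 8.5 Fr x 25 cm, stretches 1.11/1.14,
# K = 0.4 cmH2O/mL) and saline at 1 cP.

ref_fluid <- function() fluid_properties(1e-3)

ref_params <- function(sheath_label = NULL,
                       irrigation_pressure = cmH2O_to_Pa(150),
                       initial_pressure = 0) {
  sheath <- if (is.null(sheath_label)) NULL else sheath_from_label(sheath_label)
  res <- compute_resistances(default_ureteroscope(), default_anatomy(),
                             sheath, ref_fluid())
  circuit_parameters(res, default_anatomy()$stiffness, irrigation_pressure,
                     initial_pressure)
}

# randomized but physically valid circuit parameters for property sweeps
random_params <- function() {
  circuit_parameters(
    resistance_set(inflow = 10^runif(1, 9, 11),
                   outflow = 10^runif(1, 9, 11),
                   withdrawal = 10^runif(1, 8, 10)),
    stiffness = cmH2O_per_mL_to_Pa_per_m3(runif(1, 0.1, 1)),
    irrigation_pressure = cmH2O_to_Pa(runif(1, 50, 250)),
    initial_pressure = cmH2O_to_Pa(runif(1, 0, 20)))
}

# independent numerical oracle for a whole protocol: integrates the
# phase-switching governing ODE phase by phase with deSolve, never touching
# the closed-form solutions used by simulate_protocol()
ode_protocol_oracle <- function(prot, params, dt = 1) {
  r <- params$resistances
  k <- params$stiffness
  p <- params$initial_pressure
  t0 <- 0
  times <- numeric(0); pressures <- numeric(0)
  for (ph in prot$phases) {
    tloc <- seq(0, ph$duration, by = dt)
    if (tloc[length(tloc)] < ph$duration) tloc <- c(tloc, ph$duration)
    rhs <- if (ph$kind == "inserted") {
      function(t, y, parms) {
        list(k * ((params$irrigation_pressure - y[1]) / r$inflow -
                    y[1] / r$outflow))
      }
    } else {
      function(t, y, parms) list(-k * y[1] / r$withdrawal)
    }
    sol <- deSolve::ode(c(P = p), tloc, rhs, NULL, rtol = 1e-10, atol = 1e-8)
    keep <- if (t0 == 0) seq_len(nrow(sol)) else -1
    times <- c(times, t0 + sol[keep, "time"])
    pressures <- c(pressures, sol[keep, "P"])
    p <- unname(sol[nrow(sol), "P"])
    t0 <- t0 + ph$duration
  }
  list(times = times, pressures = pressures)
}
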