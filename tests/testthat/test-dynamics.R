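test_that("plateau pressure and time constants take their closed forms", {
  # sheathless representative configuration plateaus near 80% of P_irr
  p <- ref_params(NULL)
  expect_equal(steady_state_pressure(p) / p$irrigation_pressure, 0.80,
               tolerance = 0.07)
  expect_lt(steady_state_pressure(p), p$irrigation_pressure)

  # symmetric resistances split the irrigation pressure in half
  sym <- circuit_parameters(resistance_set(1e10, 1e10, 1e9),
                            cmH2O_per_mL_to_Pa_per_m3(0.4), cmH2O_to_Pa(150))
  expect_equal(steady_state_pressure(sym), cmH2O_to_Pa(75))
  # vanishing inflow resistance transmits the full irrigation pressure
  lop <- circuit_parameters(resistance_set(1, 1e12, 1e9),
                            cmH2O_per_mL_to_Pa_per_m3(0.4), cmH2O_to_Pa(150))
  expect_equal(steady_state_pressure(lop) / lop$irrigation_pressure, 1,
               tolerance = 1e-6)

  # 10/12 Fr representative configuration: rise ~2.3 min, decay ~2.5 min
  p12 <- ref_params("10/12")
  expect_equal(rise_time(p12) / 60, 2.3, tolerance = 0.02)
  expect_equal(decay_time(p12) / 60, 2.5, tolerance = 0.02)
  expect_lt(rise_time(p12), p12$resistances$inflow / p12$stiffness)

  # tau_in halves when the stiffness doubles; Rout -> infinity gives Rin/K
  stiff <- circuit_parameters(p12$resistances, 2 * p12$stiffness,
                              p12$irrigation_pressure)
  expect_equal(rise_time(stiff), rise_time(p12) / 2)
  open <- circuit_parameters(resistance_set(1e10, 1e20, 1e9),
                             cmH2O_per_mL_to_Pa_per_m3(0.4), cmH2O_to_Pa(150))
  expect_equal(rise_time(open), 1e10 / open$stiffness, tolerance = 1e-9)
  # tau_out = Rw/K is independent of the irrigation pressure
  alt <- circuit_parameters(p12$resistances, p12$stiffness, cmH2O_to_Pa(999))
  expect_identical(decay_time(alt), decay_time(p12))
})

test_that("closed-form insertion and withdrawal solutions behave at landmarks", {
  p <- ref_params("10/12", initial_pressure = cmH2O_to_Pa(5))
  tau <- rise_time(p)
  p_max <- steady_state_pressure(p)
  expect_equal(insertion_pressure(0, p), p$initial_pressure)
  expect_equal(insertion_pressure(1e9, p), p_max)
  p0 <- ref_params("10/12")
  expect_equal(insertion_pressure(rise_time(p0), p0),
               (1 - exp(-1)) * steady_state_pressure(p0))
  expect_error(insertion_pressure(-1, p), "non-negative")

  tau_out <- decay_time(p)
  p_r <- cmH2O_to_Pa(60)
  expect_equal(withdrawal_pressure(100, 100, p_r, tau_out), p_r)
  expect_equal(withdrawal_pressure(100 + tau_out, 100, p_r, tau_out),
               p_r / exp(1))
  expect_error(withdrawal_pressure(50, 100, p_r, tau_out), ">= t_r")

  # strictly monotone toward the plateau from either side
  tgrid <- seq(0, 6 * tau, length.out = 200)
  rising <- insertion_pressure(tgrid, p0)
  expect_true(all(diff(rising) > 0) && all(rising < steady_state_pressure(p0)))
  high <- ref_params("10/12", initial_pressure = cmH2O_to_Pa(120))
  falling <- insertion_pressure(tgrid, high)
  expect_true(all(diff(falling) < 0))
  expect_true(all(falling > steady_state_pressure(high)))
})

test_that("running mean equals the exact integral of the rise solution", {
  p <- ref_params("10/12", initial_pressure = cmH2O_to_Pa(8))
  # limits: mean of an instant is P_0; the plateau dominates eventually
  expect_equal(running_mean_pressure(1e-9, p), p$initial_pressure,
               tolerance = 1e-6)
  expect_equal(running_mean_pressure(1e9, p), steady_state_pressure(p),
               tolerance = 1e-6)
  expect_error(running_mean_pressure(0, p), "positive")

  # quadrature oracle: trapezoid rule on a fine grid
  for (t_end in c(60, 300, 1200)) {
    tgrid <- seq(0, t_end, length.out = 20001)
    pa <- insertion_pressure(tgrid, p)
    trapz <- sum((pa[-1] + pa[-length(pa)]) / 2 * diff(tgrid)) / t_end
    expect_equal(running_mean_pressure(t_end, p), trapz, tolerance = 1e-6)
  }
})

test_that("the numerical ODE oracle agrees with every closed form", {
  p <- ref_params("10/12")
  tgrid <- seq(0, 1800, by = 10)
  ins <- integrate_ode(p, "inserted", tgrid)
  expect_equal(ins$pressures, insertion_pressure(tgrid, p),
               tolerance = 1e-6)

  p_r <- insertion_pressure(1800, p)
  pw <- circuit_parameters(p$resistances, p$stiffness, p$irrigation_pressure,
                           p_r)
  wd <- integrate_ode(pw, "withdrawn", tgrid, initial_pressure = p_r)
  expect_equal(wd$pressures,
               withdrawal_pressure(tgrid, 0, p_r, decay_time(p)),
               tolerance = 1e-6)

  # degenerate source: zero irrigation is disallowed by the type, but a zero
  # initial pressure with withdrawal dynamics stays identically zero
  z <- integrate_ode(pw, "withdrawn", tgrid, initial_pressure = 0)
  expect_true(all(z$pressures == 0))

  # randomized property sweep across physically valid parameters
  set.seed(42)
  for (i in 1:20) {
    rp <- random_params()
    tg <- seq(0, 5 * rise_time(rp), length.out = 40)
    num <- integrate_ode(rp, "inserted", tg)
    expect_equal(num$pressures, insertion_pressure(tg, rp), tolerance = 1e-6)
    tg2 <- seq(0, 5 * decay_time(rp), length.out = 40)
    start <- rp$irrigation_pressure * 0.5
    num2 <- integrate_ode(rp, "withdrawn", tg2, initial_pressure = start)
    expect_equal(num2$pressures,
                 withdrawal_pressure(tg2, 0, start, decay_time(rp)),
                 tolerance = 1e-6)
    # exact mean vs fine trapezoid on the rise
    t_end <- 3 * rise_time(rp)
    tf <- seq(0, t_end, length.out = 5001)
    pa <- insertion_pressure(tf, rp)
    trapz <- sum((pa[-1] + pa[-length(pa)]) / 2 * diff(tf)) / t_end
    expect_equal(running_mean_pressure(t_end, rp), trapz, tolerance = 1e-6)
  }
})

test_that("mass balance: K times net inflow volume equals the pressure change", {
  p <- ref_params("10/12", initial_pressure = cmH2O_to_Pa(3))
  tgrid <- seq(0, 900, length.out = 10001)
  pa <- insertion_pressure(tgrid, p)
  q_in <- (p$irrigation_pressure - pa) / p$resistances$inflow
  q_out <- pa / p$resistances$outflow
  net <- q_in - q_out
  vol <- sum((net[-1] + net[-length(net)]) / 2 * diff(tgrid))
  expect_equal(p$stiffness * vol, pa[length(pa)] - pa[1], tolerance = 1e-6)
})

test_that("plateau pressure decreases strictly with sheath lumen diameter", {
  scope <- default_ureteroscope()
  anat <- default_anatomy()
  plateaus <- vapply(seq(8, 16, by = 0.5), function(fr) {
    res <- compute_resistances(scope, anat, access_sheath(french_to_meters(fr)),
                               ref_fluid())
    steady_state_pressure(circuit_parameters(res, anat$stiffness,
                                             cmH2O_to_Pa(150)))
  }, 0)
  expect_true(all(diff(plateaus) < 0))
})

test_that("nondimensional rescaling collapses linearly related traces", {
  p150 <- ref_params("10/12", irrigation_pressure = cmH2O_to_Pa(150))
  p200 <- ref_params("10/12", irrigation_pressure = cmH2O_to_Pa(200))
  tgrid <- seq(1, 1200, by = 1)
  tr150 <- pressure_trace(tgrid, insertion_pressure(tgrid, p150))
  tr200 <- pressure_trace(tgrid, insertion_pressure(tgrid, p200))
  n150 <- nondimensionalize(tr150, p150$irrigation_pressure, rise_time(p150))
  n200 <- nondimensionalize(tr200, p200$irrigation_pressure, rise_time(p200))
  expect_lt(max(abs(n150$pressures - n200$pressures)), 1e-12)

  # scaling by the per-curve plateau reduces any zero-baseline rise to 1-e^-t
  nmax <- nondimensionalize(tr150, steady_state_pressure(p150), rise_time(p150))
  expect_equal(nmax$pressures, 1 - exp(-nmax$times), tolerance = 1e-12)

  # identity scales change nothing
  ident <- nondimensionalize(tr150, 1, 1)
  expect_identical(ident$pressures, tr150$pressures)
  expect_error(nondimensionalize(tr150, 0, 1), "positive")
})

test_that("traces export as CSV with unit-bearing headers", {
  p <- ref_params("10/12")
  tgrid <- seq(0, 60, by = 10)
  tr <- pressure_trace(tgrid, insertion_pressure(tgrid, p))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  expect_identical(readLines(path, n = 1), "time_s,pressure_cmH2O,phase")
  back <- utils::read.csv(path)
  expect_equal(back$pressure_cmH2O, Pa_to_cmH2O(tr$pressures))
  expect_equal(back$time_s, tgrid)
})
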