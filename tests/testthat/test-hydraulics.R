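test_that("circular Poiseuille resistance matches hand-evaluated values", {
  # 3.6 Fr working channel over 67 cm of scope, saline
  expect_equal(circular_resistance(0.67, 1.2e-3, 1e-3), 1.3165e10,
               tolerance = 1e-3)
  # nominal 1.3 Fr UPJ over 0.5 cm
  expect_equal(circular_resistance(0.005, french_to_meters(1.3), 1e-3),
               5.7775e9, tolerance = 1e-3)
  # fourth-power diameter scaling
  expect_equal(circular_resistance(0.1, 1e-3, 1e-3) /
                 circular_resistance(0.1, 2e-3, 1e-3), 16)
  expect_error(circular_resistance(-0.1, 1e-3, 1e-3), "positive")
  expect_error(circular_resistance(0.1, 0, 1e-3), "positive")
})

test_that("annular effective d^4 has the right value, limits and bounds", {
  # 10 Fr sheath lumen around a 7.5 Fr scope
  expect_equal(annular_effective_d4(french_to_meters(10), french_to_meters(7.5)),
               2.2536e-12, tolerance = 1e-3)
  # circular limit: log term vanishes as the inner cylinder shrinks
  d_o <- 3e-3
  expect_equal(annular_effective_d4(d_o, 0), d_o^4)
  expect_equal(annular_effective_d4(d_o, d_o * 1e-3), d_o^4,
               tolerance = 1e-3)
  # gap-closing limit
  expect_lt(annular_effective_d4(d_o, d_o * (1 - 1e-6)), 1e-6 * d_o^4)
  # the log term is a strictly positive correction
  for (ratio in c(0.1, 0.5, 0.75, 0.99)) {
    expect_lt(annular_effective_d4(d_o, ratio * d_o), d_o^4 - (ratio * d_o)^4)
  }
  # monotone increasing in the outer diameter at fixed inner diameter
  d_outer <- seq(2.6e-3, 6e-3, length.out = 50)
  vals <- vapply(d_outer, annular_effective_d4, 0, d_inner = 2.5e-3)
  expect_true(all(diff(vals) > 0))
  expect_error(annular_effective_d4(2.5e-3, 2.5e-3), "degenerate annulus")
  expect_error(annular_effective_d4(2.5e-3, 3e-3), "degenerate annulus")
})

test_that("annular resistance is consistent with the circular limit and length-linear", {
  expect_equal(annular_resistance(0.35, french_to_meters(10),
                                  french_to_meters(7.5), 1e-3),
               6.3278e9, tolerance = 1e-3)
  expect_equal(annular_resistance(0.35, 3e-3, 0, 1e-3),
               circular_resistance(0.35, 3e-3, 1e-3))
  expect_equal(annular_resistance(0.35, 3e-3, 2e-3, 1e-3),
               2 * annular_resistance(0.175, 3e-3, 2e-3, 1e-3))
})

test_that("distended diameters scale the shaft by the stretch factor", {
  expect_equal(stretched_diameter(2.5e-3, 1.14), 2.85e-3)
  expect_equal(stretched_diameter(2.5e-3, 1.11), 2.775e-3)
  expect_equal(stretched_diameter(2.5e-3, 1), 2.5e-3)
  expect_error(stretched_diameter(2.5e-3, 0.9), ">= 1")
})

test_that("circuit resistances reproduce the representative configuration", {
  scope <- default_ureteroscope()
  anat <- default_anatomy()
  mu <- ref_fluid()

  expect_equal(inflow_resistance(scope, mu), 1.3165e10, tolerance = 1e-3)
  # doubling the working length doubles the inflow resistance
  scope2 <- ureteroscope(scope$shaft_diameter, scope$channel_diameter,
                         2 * scope$working_length)
  expect_equal(inflow_resistance(scope2, mu), 2 * inflow_resistance(scope, mu))

  # sheathless: annular UPJ + annular ureter, both distended around the shaft
  expect_equal(outflow_resistance(scope, anat, NULL, mu), 6.9375e10,
               tolerance = 1e-3)
  # 10/12 Fr sheath: annular UPJ + annular sheath lumen
  expect_equal(outflow_resistance(scope, anat, sheath_from_label("10/12"), mu),
               9.1128e9, tolerance = 1e-3)
  # series decomposition against the primitive segment resistances
  d_sc <- scope$shaft_diameter
  by_hand <- annular_resistance(anat$upj_length, 1.11 * d_sc, d_sc, 1e-3) +
    annular_resistance(0.35, french_to_meters(10), d_sc, 1e-3)
  expect_equal(outflow_resistance(scope, anat, sheath_from_label("10/12"), mu),
               by_hand)

  # outflow resistance falls monotonically as the sheath lumen grows
  lumens <- c(8, 9, 10, 11, 12, 14)
  r <- vapply(lumens, function(fr) {
    outflow_resistance(scope, anat, access_sheath(french_to_meters(fr)), mu)
  }, 0)
  expect_true(all(diff(r) < 0))

  # withdrawal: circular nominal conduits in series
  expect_equal(withdrawal_resistance(anat, sheath_from_label("10/12"), mu),
               5.8930e9, tolerance = 1e-3)
  # a very large sheath lumen leaves only the UPJ resistance
  big <- access_sheath(0.05)
  expect_equal(withdrawal_resistance(anat, big, mu),
               circular_resistance(anat$upj_length, anat$upj_diameter, 1e-3),
               tolerance = 1e-6)
  expect_gt(withdrawal_resistance(anat, NULL, mu), 0)

  # a sheath narrower than the scope shaft is a configuration error
  expect_error(outflow_resistance(scope, anat, access_sheath(2e-3), mu),
               "does not clear")
})

test_that("two conduits in series add resistances (flow computation check)", {
  mu <- 1e-3
  r1 <- circular_resistance(0.1, 2e-3, mu)
  r2 <- circular_resistance(0.2, 1.5e-3, mu)
  dp <- 1000
  q_series <- dp / (r1 + r2)
  # same flow recovered by splitting the pressure drop across both segments
  dp1 <- q_series * r1
  dp2 <- q_series * r2
  expect_equal(dp1 + dp2, dp)
  expect_equal(dp1 / r1, dp2 / r2)
})

test_that("Whitaker inversion recovers the UPJ diameter and is exact", {
  m_min <- whitaker_measurement(cmH2O_to_Pa(15), mL_per_min_to_m3_per_s(15))
  d <- whitaker_upj_diameter(m_min, 0.005, ref_fluid())
  expect_equal(meters_to_french(d), 1.3, tolerance = 0.01)

  # the printed per-second flow rate would imply a much wider junction
  m_s <- whitaker_measurement(cmH2O_to_Pa(15), mL_per_s_to_m3_per_s(15))
  expect_equal(meters_to_french(whitaker_upj_diameter(m_s, 0.005, ref_fluid())),
               3.6, tolerance = 0.01)

  # quarter-power flow dependence: 16x the flow doubles the diameter
  m16 <- whitaker_measurement(cmH2O_to_Pa(15), 16 * mL_per_min_to_m3_per_s(15))
  expect_equal(whitaker_upj_diameter(m16, 0.005, ref_fluid()), 2 * d,
               tolerance = 1e-12)

  # exact inverse of circular_resistance composed with dP = R Q
  for (d_true in c(4e-4, 1e-3, 3e-3)) {
    r <- circular_resistance(0.005, d_true, 1e-3)
    q <- 2.5e-7
    m <- whitaker_measurement(r * q, q)
    expect_equal(whitaker_upj_diameter(m, 0.005, ref_fluid()), d_true,
                 tolerance = 1e-14)
  }
  expect_error(whitaker_measurement(-1, 1e-7), "positive")
})
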