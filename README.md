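# uroflow

Renal pelvis pressure during ureteroscopic kidney stone treatment, modelled
as a lumped-parameter hydraulic circuit.

## The problem

During ureteroscopic lithotripsy, pressurized saline is irrigated through
the working channel of the ureteroscope into the renal pelvis — the kidney's
urinary collecting chamber — and drains back out through the narrow gaps
around the scope. Sustained pressures above roughly 40 cm H₂O put the
patient at risk of pyelovenous backflow and post-operative sepsis, so
urologists care how equipment choices (scope size, ureteral access sheath
size, irrigation pressure) and technique (how often and for how long the
scope is withdrawn for stone basketing) shape the pressure over time.

`uroflow` is for biomedical engineers and computationally minded
endourologists who want those trade-offs quantified. It treats the urinary
tract as a pipe network in the laminar, quasi-static (Poiseuille) regime and
the renal pelvis as a linear compliance chamber.

## The model

Each conduit has hydraulic resistance `R = 128 μ ℓ / (π d⁴)`; annular gaps
(scope inside sheath, UPJ or ureter) use the effective fourth-power diameter

    d̃⁴ = d_o⁴ − d_i⁴ − (d_o² − d_i²)² / ln(d_o/d_i).

Mass conservation plus the linear constitutive law ΔP = K ΔV give a
first-order linear ODE for the renal pelvis gauge pressure P(t). With the
scope inserted,

    dP/dt + (K/R_in)(1 + R_in/R_out) P = (K/R_in) P_irr,

so the pressure relaxes toward the plateau `P_max = P_irr (1 + R_in/R_out)⁻¹`
with rise time `τ_in = (R_in/K)(1 + R_in/R_out)⁻¹`. After withdrawal the
tract relaxes to its nominal diameters and the pressure decays freely with
`τ_out = R_w/K`. Insertion/withdrawal schedules are simulated by chaining
these closed-form solutions with continuous pressure; time-averaged metrics
use the exact per-phase integrals. A `deSolve`-based integrator of the raw
ODE serves as an independent numerical oracle in the test suite.

## Worked example

The representative configuration — a 7.5 Fr flexible scope with a 3.6 Fr
channel through a 10/12 Fr access sheath, irrigation at 150 cm H₂O, renal
pelvis stiffness 0.4 cm H₂O/mL — simulated under the most fragmented
withdrawal strategy (ten 2-minute insertions separated by nine 1-minute
withdrawals):

```r
library(uroflow)
params <- circuit_parameters(
  compute_resistances(default_ureteroscope(), default_anatomy(),
                      sheath_from_label("10/12 Fr")),
  default_anatomy()$stiffness, cmH2O_to_Pa(150))
params
#> <circuit_parameters> P_irr 150.0 cmH2O, P_0 0.0 cmH2O, K 0.40 cmH2O/mL
#> <resistance_set> Rin 1.316e+10, Rout 9.113e+09, Rw 5.893e+09 Pa.s/m^3
#>   plateau 40.9% of P_irr, tau_in 2.29 min, tau_out 2.50 min

tr <- simulate_protocol(reference_protocols()$option4, params)
tr
#> <pressure_trace> 1741 samples over 29.0 min, peak 49.7 cmH2O

tab <- strategy_sweep(list("10/12", "11/13", "12/14"),
                      unname(reference_protocols()))
tab[which.max(tab$relative_decrease_pct), ]
#>  sheath_label          protocol_name mean_pressure_cmH2O peak_pressure_cmH2O
#>      10/12 Fr 2 min x 10 / 1 min x 9            39.44764            49.65543
#>  relative_decrease_pct total_time_min
#>               27.40934             29
```

Reading: with this sheath the pressure plateaus at 40.9% of the irrigation
pressure (≈61 cm H₂O if never withdrawn). The fragmented schedule caps the
peak at 49.7 cm H₂O and cuts the time-averaged pressure by 27% relative to
the no-withdrawal baseline — at the cost of 9 extra minutes of operative
time. The benefit shrinks for larger sheaths, whose plateaus sit below the
backflow threshold anyway.

A command-line runner is installed alongside the package
(`exec/uroflow`): `uroflow run --config cfg.yaml`,
`uroflow sweep --config sweep.yaml --out sweep.csv`, and
`uroflow fixtures --out dir`, which emits ready-made YAML configurations
for every bundled scenario. See `vignettes/pressure-model.Rmd` for the full
account of the model, its parameters and its limitations.

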