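---
title: "A lumped-parameter model of renal pelvis pressure during ureteroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of renal pelvis pressure during ureteroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uroflow)
```

## The physical picture

During ureteroscopic lithotripsy, saline is driven at a set irrigation
pressure $P_{irr}$ through the scope's working channel into the renal
pelvis, and drains back out through whatever gaps remain around the scope:
the distended ureteropelvic junction (UPJ), and then either the lumen of a
ureteral access sheath or the ureter itself. The renal pelvis is an elastic
chamber: retained volume raises its pressure through a linear constitutive
law $\Delta P = K\,\Delta V$.

`uroflow` models this as a two-resistor compliance circuit. All conduits
operate in the laminar, quasi-static Poiseuille regime (Reynolds numbers
and Womersley numbers are small at clinical flow rates), so each conduit is
a hydraulic resistance $R = 128\mu\ell/(\pi d^4)$; for an annular gap, $d^4$
is replaced by the effective fourth-power diameter

$$\tilde d^4 = d_o^4 - d_i^4 - \frac{(d_o^2 - d_i^2)^2}{\ln(d_o/d_i)},$$

which recovers $d_o^4$ as the inner cylinder vanishes and closes to zero as
the gap closes (`annular_effective_d4()` refuses a degenerate annulus
outright rather than clamping, because a silently infinite resistance would
mask a mis-specified device pairing).

Mass conservation, $K\,(Q_{in}-Q_{out}) = dP/dt$, with Poiseuille inflow and
outflow, gives a linear first-order ODE. With the scope inserted the gauge
pressure relaxes exponentially toward a plateau that is a fixed fraction of
the irrigation pressure,

$$P(t) = P_{max}\left(1 - e^{-t/\tau_{in}}\right) + P_0\,e^{-t/\tau_{in}},
\qquad P_{max} = \frac{P_{irr}}{1 + R_{in}/R_{out}}, \qquad
\tau_{in} = \frac{R_{in}/K}{1 + R_{in}/R_{out}}.$$

When the scope is withdrawn (e.g. to basket a stone fragment) irrigation
stops, the UPJ and drainage conduit relax to their nominal circular
cross-sections, and the pressure decays freely with
$\tau_{out} = R_w/K$. Two structural consequences the package leans on:
the plateau depends only on the resistance *ratio* (never on $K$), and the
stiffness only sets the timescales.

## Parameters, units and defaults

Internally everything is SI (m, Pa, Pa·s, m³/s, s); clinical units —
French gauge (3 Fr = 1 mm), cm H₂O (98.1 Pa), cP, mL/min — are accepted
only at the boundaries (`parse_quantity()`, the conversion helpers, the
YAML configuration loader). One motivation for this discipline is that
mixed-unit stiffness constants are notoriously easy to mangle: the correct
factor is 1 cm H₂O/mL = 9.81×10⁷ Pa/m³, and slips of many orders of
magnitude survive casual inspection.

The representative defaults (`default_ureteroscope()`, `default_anatomy()`):

| parameter | default | note |
|---|---|---|
| scope shaft | 7.5 Fr | benchmark flexible scope tip diameter, taken as uniform along the shaft |
| working channel | 3.6 Fr × 67 cm | sets $R_{in}$ |
| sheath | 10/12, 11/13, 12/14, 14/16 Fr × 35 cm | dual label = inner lumen / outer; the *inner* lumen governs the annular return flow |
| UPJ | 1.3 Fr × 0.5 cm nominal | nominal diameter from the Whitaker inversion (below) |
| ureter | 8.5 Fr × 25 cm nominal | used when no sheath is placed |
| stretch factors | 1.11 (UPJ), 1.14 (ureter) | distended diameters as multiples of the shaft diameter while inserted; calibrated against ex-vivo porcine data, configurable |
| stiffness $K$ | 0.4 cm H₂O/mL | mean of published pressure–volume measurements; quoted with an uncertainty of ±0.3, easily the least certain input (one source prints 0.41; we use 0.4) |
| viscosity | 1 cP | saline |

**The Whitaker inversion.** The nominal UPJ diameter comes from treating
the unobstructed upper tract as one circular conduit at the standard
urodynamic operating point, $d = (128\mu\ell Q/\pi\Delta P)^{1/4}$. The
operating point is 15 cm H₂O of pressure drop at a perfusion rate of
15 mL/min; that rate is sometimes misprinted as 15 mL/s, which would imply
a 3.6 Fr junction instead of 1.3 Fr. `whitaker_upj_diameter()` takes an
explicit flow rate so both readings can be computed; the package default
operating point uses mL/min, which is the reading consistent with the
1.3 Fr value used everywhere else.

## Protocol simulation

A protocol is an alternating sequence of inserted and withdrawn phases,
beginning and ending inserted (`protocol()`, `periodic_protocol()`).
`simulate_protocol()` chains the closed-form phase solutions with pressure
continuity at each boundary; reinsertion is instantaneous (the model has
only two states, so transition dynamics are not represented). During a
withdrawal the irrigation is off — there is no source term — and resumption
coincides exactly with reinsertion.

Averaged metrics are *exact*: each phase contributes its analytic integral
($P_{max}T - \tau_{in}(P_{max}-P_0)(1-e^{-T/\tau_{in}})$ inserted,
$P_r\tau_{out}(1-e^{-T/\tau_{out}})$ withdrawn), so
`time_averaged_pressure()` is invariant under resampling, and
`time_above_threshold()` solves the crossing times in closed form. The
running time average of a single rise is implemented as the exact integral
$\bar P(t) = P_{max} - (P_{max}-P_0)\,\frac{1-e^{-t/\tau_{in}}}{t/\tau_{in}}$;
note the minus sign on the transient term, which one sometimes sees typeset
with the opposite sign — the limit $\bar P(t\to 0^+) = P_0$ fixes it
unambiguously. Numerically the transient factor uses `expm1` to stay
accurate as $t \to 0$.

The four reference strategies (`reference_protocols()`) share 20 minutes of
cumulative inserted time: no withdrawal (20 min total); 2 × 10 min with one
5-min withdrawal (25 min); 5 × 4 min with four 2-min withdrawals (28 min);
10 × 2 min with nine 1-min withdrawals (29 min). `strategy_sweep()` crosses
them with sheath sizes and reports each option's time-averaged pressure
decrease relative to the no-withdrawal baseline.

**Averaging window.** The baseline-relative decrease can be computed over
the full timeline (insertions plus withdrawals) or over inserted time only;
the sources of the reference comparison do not state their convention.
The default is the full procedure, since that is what the plotted timelines
span; both windows are exposed, and for the headline case they differ by
under two percentage points of the plateau pressure (asserted in the test
suite), so the ambiguity is immaterial.

## Scenario generators

The package bundles two scenario sets, each a first-class generator rather
than stored data:

* `sheath_comparison_scenarios()` — the eight-curve set: {no sheath, 10/12,
  12/14, 14/16 Fr} × {150, 200 cm H₂O}, zero baseline pressure. (One
  published description of this set labels the dotted curves 100 cm H₂O
  while the accompanying text says 150; the generator follows the text.)
* `validation_scenarios()` — thirteen runs reconstructing two published
  clinical data sets: four flexible-scope runs after Rehman *et al.* (the
  benchmark scope at 200 cm H₂O; no sheath plus three sheath sizes — the
  exact four sheath conditions are not enumerated in the source, so
  no-sheath + 10/12 + 12/14 + 14/16 is assumed) and nine semirigid runs
  after Shao *et al.* (8 Fr scope, ureteral stones at three locations ×
  three irrigation pressures, nonzero baseline pressure). Values the
  sources omit are shipped as overridable, documented defaults — the
  semirigid scope's 5 Fr channel and 31.5 cm length, irrigation pressures
  {200, 150, 100} cm H₂O, stone locations {5, 12.5, 25} cm from the
  ureteral orifice, and a 10 cm H₂O baseline, all chosen once as
  clinically typical values. The model's collapse structure does not
  depend on them.

For a stone treated *in* the ureter, the scope stops at the stone and the
return path is the annular gap between the distended ureter and the scope
over the inserted length; `stone_path_resistance()` is linear in the
stone's distance from the ureteral orifice and reduces to the sheathless
ureter segment for a proximal stone.

**What these scenarios do and do not emulate.** They reproduce the study
*conditions* — device geometry, pressures, schedules — under this model's
assumptions. Passing tests therefore demonstrate internal consistency
(closed forms vs the ODE, exact collapse behaviour, schedule arithmetic),
not agreement with any patient: real procedures involve peristalsis,
pressure-dependent compliance, bladder outlet effects for sheathless cases,
and surgeon behaviour, none of which are modelled.

## Nondimensionalization

Rescaling each curve's pressure by a characteristic pressure and time by
its rise time collapses families of solutions. `collapse_check()` evaluates
all scenarios on a shared dimensionless grid ($\hat t \in [0.025, 5]$,
200 points — starting just above zero because the running mean is defined
as a limit there) and reports the maximal pairwise pointwise deviation plus
the number of distinct curve groups at a $10^{-9}$ tolerance. Zero-baseline
scenarios scaled by their own plateau collapse to machine precision, since
every such solution is exactly $1 - e^{-\hat t}$; scaling by the irrigation
pressure instead groups curves by their resistance ratio (four groups for
the eight-curve set); nonzero baselines leave a small residual — the
"nearly collapses" of the thirteen-curve validation set.

## Numerical choices

* The `deSolve` (lsoda) integration of the raw governing ODE is the
  *oracle*, not the engine: the simulator uses the closed forms. Default
  oracle tolerances are rtol $10^{-9}$, atol $10^{-6}$ Pa — far below any
  model-relevant pressure scale. Tests require closed-form/oracle agreement
  to a relative $10^{-6}$ across randomized valid parameters, and
  whole-protocol agreement (phase-switching integration) to $10^{-5}$.
* Property sweeps draw resistances log-uniformly over
  $10^{9}$–$10^{11}$ Pa·s/m³ ($10^{8}$–$10^{10}$ for the withdrawal path),
  stiffness 0.1–1 cm H₂O/mL, irrigation 50–250 cm H₂O, baselines
  0–20 cm H₂O, under fixed seeds — spanning the physically plausible range
  around the defaults. Suite-wide problem sizes (20-run sweeps, $10^4$-point
  quadrature grids) keep the whole test run in a few seconds.
* Pressures are gauge with baseline zero; the model never produces negative
  pressures from non-negative initial conditions, and traces clamp at zero
  only to guard floating-point undershoot in the oracle.
* $K$ is constant within a run; it varies only across configurations.

## Known limitations

No turbulence or entrance corrections; no compliant (pressure-dependent)
conduit diameters, peristalsis, or viscoelastic/Neo-Hookean tissue response;
no bladder outlet resistance or filling for sheathless drainage; no
inertial terms. The stiffness uncertainty (±0.3 around 0.4 cm H₂O/mL)
propagates directly into every timescale (though not into plateau levels),
and should be treated as the dominant error source in any clinical reading
of the outputs.
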