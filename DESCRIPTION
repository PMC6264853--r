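Package: uroflow
Title: Lumped-Parameter Modelling of Renal Pelvis Pressure During Ureteroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates the renal pelvis pressure during ureteroscopic kidney
    stone treatment with a lumped-parameter hydraulic circuit: Poiseuille
    resistances of the scope working channel, ureteral access sheath, ureter
    and ureteropelvic junction, a linear compliance law for the renal pelvis,
    and closed-form solutions of the resulting first-order pressure dynamics.
    Includes piecewise simulation of scope insertion/withdrawal protocols,
    time-averaged pressure metrics, nondimensional curve-collapse checks,
    scenario generators reproducing published ex-vivo and in-vivo study
    conditions, a unit-aware configuration format and a command-line runner.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
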