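# ventsplit

Lumped-parameter simulation of one pressure-controlled ventilator supporting
two patients through a T-piece splitter.

## What it is for

In a severe ventilator shortage, splitting one machine between two patients
has been proposed as a last resort. The core difficulty is mismatched
respiratory mechanics: ARDS lowers lung compliance with disease severity, and
a plain splitter delivers the same pressure waveform to both patients, so the
stiffer lung receives a smaller tidal volume with no per-patient control.
`ventsplit` is a simulation tool for engineers and physiologists studying this
problem. It quantifies the tidal-volume imbalance of the standard splitter and
evaluates a modified splitter — an adjustable flow restrictor in each
inspiration arm plus a one-way valve in each expiration arm — that restores
independent control of each patient's tidal volume.

This package is a physics and calibration sandbox, **not** a clinical
recommendation: ventilating two patients from one machine is strongly advised
against whenever any alternative exists.

## The model

Respiratory mechanics are simulated through the standard electrical analogue:
volume ↔ charge, flow ↔ current, pressure ↔ voltage, tube ↔ resistor,
lung + chest wall ↔ capacitor, one-way valve ↔ diode. Each patient is a series
RC branch (R_ETT = 8, R_L = 2 cmH2O/L/s, C_L to ground); the ventilator is a
square-wave source (PIP during inspiration, PEEP during expiration, period
60/RR split by the I:E ratio) feeding the splitter arms (R_I = R_E = 0.06
cmH2O/L/s per arm). Lung presets A–D reduce the healthy compliance
0.054 L/cmH2O by 0/20/30/40% to represent increasing ARDS severity.

The state variables are the compliance pressures; at each instant the
remaining resistive network is solved by nodal analysis with ideal-diode
conduction states resolved self-consistently, and `deSolve` integrates
dP_c/dt = I_c/C with restarts at every phase edge. For a decoupled branch the
periodic steady state has the closed form

    VT = 1000 · C · ΔP · (1 − a)(1 − b) / (1 − ab),
    a = exp(−t_insp/τ_insp),  b = exp(−t_exp/τ_exp),  τ = R·C,

which the package carries as an independent cross-check (`steady_state_vt()`).

## Worked example

Pair a healthy patient (Lung Model A) with increasingly severe ARDS partners
on the standard splitter, at the PIP that ventilates the healthy patient
correctly:

```r
library(ventsplit)
tab <- run_standard_mismatch()
tab[, c("pair", "pip", "vt1_ml", "vt2_ml", "deficit_pct")]
#>   pair  pip vt1_ml vt2_ml deficit_pct
#> 1  A-A 15.0  490.3  490.3         0.0
#> 2  A-B 15.0  490.3  411.0        16.2
#> 3  A-C 15.0  490.3  366.3        25.3
#> 4  A-D 15.0  490.4  318.4        35.1
#> 5  B-C 17.0  493.3  439.6        10.9
#> 6  B-D 17.0  493.3  382.2        22.5
#> 7  C-D 18.5  494.6  429.9        13.1
```

Patient 1 always receives ~490 ml, while the stiffer patient 2 is starved —
down to a 35% shortfall in the extreme A–D pairing. The modified splitter
fixes this: calibrate it from scratch for the A–D pair,

```r
tune_modified(lung_preset("A"), lung_preset("D"))
#> Tuned settings: PIP 20.380 cmH2O, R_V1 17.432, R_V2 0.000 cmH2O/L/s
#> Achieved tidal volumes: 490.1 / 489.8 ml (target 490; converged after 25 evaluations)
```

i.e. raise PIP until the stiff patient reaches 490 ml, then restrict the
healthy patient's inspiration arm (~17 cmH2O/L/s) to bring them down to the
same volume. `adjust_patient2()` similarly raises or lowers one patient's
volume by ±30% while holding the other. Low-level building blocks
(`build_standard()`, `build_modified()`, `simulate_circuit()`,
`cycle_summaries()`) expose the traces behind these summaries, and
`inst/exec/ventsplit` provides the same verbs on the command line:

```sh
ventsplit simulate --config inst/extdata/example_config.yaml --cycles 8 --out traces.csv
ventsplit reproduce standard-mismatch --out table.csv
ventsplit adjust --pair C,C --delta -0.30
```

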