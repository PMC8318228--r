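# epimech

Deformable-cell biomechanics of epithelial morphogenesis in R.

`epimech` is a sub-cellular element simulator for questions of the kind
"can purely mechanical cell behaviours explain this tissue shape change?".
Each epithelial cell is a closed triangulated membrane of particles (34 or
42) plus one intracellular particle; all connections are non-linear Morse
springs,

F = 2 J ρ (e^{2ρ(r − r_eq)} − e^{ρ(r − r_eq)}) û,

and particles follow overdamped first-order dynamics λ v = ΣF.  Cell
behaviours — elongation, apical constriction, repulsion-driven
lumenogenesis — are programmed as retargetings of spring equilibrium
lengths r_eq; neighbouring cells are coupled by distance-based adhesion
links that transmit forces between apposed membranes.  The elastic energy
E = Σ_springs (r_eq − r)² measures how far cells are from their resting
state.

The shipped scenarios reproduce mouse peri-implantation mechanics: a
rosette-shaped epiblast (EPI) built by polarised apical constriction, a
trophectoderm (TE) cap draped over it whose cells elongate and then
constrict apically with a positional step profile, lumenogenesis by
apical-membrane separation and repulsion, and TE–EPI detachment.  Slice
metrics (interface curvature θ, interface length/diameter ratio L/D,
pushing distances, lumen volume) and an in-silico stress–strain protocol
(Young modulus Y from the slope of σ = F/S against ε = ΔL/L0) quantify
the outcomes, and a normalised fitness M combines θ, L/D and pushing
distance across TE-stiffness sweeps.

## Worked example

Single-cell stiffness calibration, then the implantation experiment with
TE detachment:

```r
library(epimech)

# Emergent stiffness of one columnar 34-vertex cell at J = 2.5
res <- stress_strain_protocol()
res
#> stress_strain_result: Y = 89.8112 (intercept -0.0125, R = 0.9999), 10 loads, tensile
```

The fitted slope `Y` is the cell's Young modulus in model units: the
ratio of axial stress σ = F/S to strain ΔL/L0 at equilibrium.  It scales
exactly linearly in the interaction strength `J` (the Morse spring
stiffness is 2Jρ²) and its absolute value is a property of the mesh
layout; `R = 0.9999` says the ten loads stay in the linear regime.

```r
run <- run_scenario(implantation_scenario("implantation-detach"))
tail(run$metrics[, c("t", "E", "theta", "ratio", "pd_lowest")], 4)
#>       t        E    theta    ratio pd_lowest
#> 16 7500 2.882546 157.3369 1.034794 0.1973621
#> 17 8000 2.795978 157.0720 1.035405 0.1955671
#> 18 8500 2.733397 156.9619 1.035667 0.1941616
#> 19 9000 2.695882 156.9117 1.035786 0.1929321
```

During TE morphogenesis (steps 0–6000) the interface curvature θ rises
from 136° towards a flat angle and L/D falls towards 1 as the epiblast
top is pressed into a cup, while the epiblast is pushed towards the
maternal side (`pd_lowest` > 0).  After the TE is detached at step 6000
the epiblast springs back (θ drops) and the population's elastic energy E
falls below every earlier plateau: the cells were being held away from
their resting state by the trophectoderm.

Scenario presets (`implantation`, `implantation-detach`,
`implantation-no-lumen`, `lumenogenesis`, `stress-strain`) can also be run
from a config file, writing metric CSVs, VTK/OBJ snapshots and a
provenance record:

```r
run(run_config("implantation"))           # or run("inst/configs/implantation.yaml")
```

A thin CLI lives in `inst/cli/epimech` (verbs `run`, `calibrate`,
`plot`).

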