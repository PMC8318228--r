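---
title: "Methods: a sub-cellular element model of epithelial morphogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a sub-cellular element model of epithelial morphogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epimech)
```

## The model

`epimech` implements a sub-cellular element model (SEM) of epithelial
cells.  Each cell is a closed triangulated membrane of particles — four or
five octagonal rings of eight particles plus an apical and a basal pole
(34 or 42 membrane particles) — together with a single intracellular
particle at the centroid, standing in for the microtubule-organising
centre.  Two membrane particles of the same cell are *internal neighbours*
when they share a mesh triangle; every internal-neighbour pair, and every
membrane-to-intracellular pair, is connected by a non-linear spring whose
force derives from a Morse potential:

$$ F = 2 J \rho \left( e^{2\rho (r - r_{eq})} - e^{\rho (r - r_{eq})} \right) $$

directed along the line joining the particles.  The force vanishes at the
equilibrium length $r_{eq}$, resists both extension and compression, and
has the asymmetry typical of Morse interactions: exponentially stiffening
under extension, bounded under compression.  At construction every
$r_{eq}$ equals the built distance, so a freshly built cell is exactly at
rest.  The *elastic energy* of a cell is the sum over its springs of
$(r_{eq} - r)^2$; it is zero at rest and measures how far the cell is from
its resting state.

Particles obey overdamped first-order dynamics: the velocity of a membrane
particle is its total force divided by the medium friction
$\lambda_{med}$, and the intracellular particle moves under the reaction
of its cytoskeleton springs divided by $\lambda_\chi$.  There is no
inertia, no thermal noise, and no randomness anywhere: identical inputs
give bit-identical trajectories.

Cells never exert forces on each other through potentials.  Instead,
*adhesion links* between particles of neighbouring cells transmit forces:
a linked particle additionally receives its partner's internal +
cytoskeleton force sum, so apposed membranes deform together.  Cell pairs
are gated by a Moore neighbourhood on an integer lattice (up to 26
neighbours), and particle pairs within the adhesion cutoff (0.4 apical
radii) are paired nearest-first.

All cell behaviours are retargetings of equilibrium lengths: the shape a
cell "wants" is encoded in its spring targets, and the overdamped dynamics
perform the motion.  Elongation rebuilds the target template with a larger
height (and optionally a tapered apical radius); apical constriction pulls
the apical ring of the target geometry towards the pole axis, shrinking
its radius from $R$ to $R - d$; full constriction ($d = R$) collapses the
apical ring onto the pole.  Lumenogenesis breaks the adhesion pairs
between apposed apical membranes and adds a radial Morse force from a
virtual source at the apical centroid with equilibrium at the lumen radius
$R_{lum}$, so apical particles inside the shell are pushed outward —
hollowing without cell death.

## Parameters

All quantities are dimensionless model units; lengths are cell-scale
(apical radius $R = 0.5$, columnar height $h = 2$, aspect ratio 2) and a
"time step" is one integration step.

| parameter | default | meaning |
|---|---|---|
| `J_TE`, `J_EPI` | 2.5 | interaction strength per tissue; sets spring stiffness $2J\rho^2$ |
| `rho` | 1 | Morse scaling factor (inverse length) |
| `lambda_med`, `lambda_chi` | 2 | friction on membrane / intracellular particles |
| `dt` | 0.005 | Euler step |
| `force_cap_mult` | 10 | Morse force clamp at `cap * J * rho` |
| `adhesion_cutoff` | 0.2 | particle pairing distance (0.4 R) |
| `max_links` | 1 | adhesion links per particle (one-to-one pairing) |
| `refresh_every` | 10 | steps between link recomputations |
| `d` | 0.5 (= R) | apical shrinkage of constricting cells |
| `R_lum` | 0.25 | lumen radius |

## Numerical choices

Three defaults are load-bearing and were fixed by stability analysis, not
convenience:

* **Time step.** The explicit Euler scheme is stable while
  $dt \cdot k / \lambda < 2$ for every local stiffness $k$.  The stiffest
  stable configuration the package supports is the intracellular particle
  at low $\lambda_\chi$: its effective stiffness from 34 cytoskeleton
  springs is $\approx 100$, so at `dt = 0.005` the dynamics destabilise
  below $\lambda_\chi/\lambda_{med} \approx 0.13$ — the friction-ratio
  threshold reported by `sweep_friction_ratio()` is an integrator
  property, which is the intended reading: below it "the cell is not a
  physical material" for this scheme.
* **Force cap.** A stretched Morse spring stiffens exponentially; beyond
  extension $\approx 2$ its tangent stiffness would cross the Euler limit
  and a transiently overstretched spring would catapult.  Clamping the
  force magnitude at $10 J \rho$ freezes the force growth at extension
  $\approx 0.9$, well inside the stable regime, and is inactive in normal
  operation.
* **One-to-one adhesion.** Writing the transmission rule as a matrix,
  linked particles evolve under $(I + A)\,G$ where $A$ is the link
  adjacency.  For a perfect matching $I + A$ is positive semi-definite
  (eigenvalues 0 and 2: the pair's relative coordinate is frozen, its
  common coordinate relaxes).  Any chain of two or more links gives
  $I + A$ a negative eigenvalue (e.g. $1 - \sqrt2$ for a 3-chain), an
  *anti-damped* mode that pumps energy into dense contact zones until they
  collapse.  `max_links = 1` therefore pairs particles one-to-one.

Other choices: adhesion links are refreshed every 10 steps with a
deterministic nearest-first greedy assignment (ties broken by candidate
order); coincident particles on a spring abort the run naming the pair;
event times in scenarios are step counts.

## The embryo builders

`build_rosette_epiblast()` constructs the epiblast as two layers of nine
columnar cells on a 3x3 grid, each cell tilted so its apical face points
at the tissue centre (upper layer apices down, lower layer apices up),
with apical faces placed 0.15 units from the centre.  Applying full apical
constriction to every cell and relaxing for 2000 steps folds the two
layers into an oval ball — taller than wide because of the columnar cell
proportions — whose apical particles converge at the centre: a rosette
with no cavity.  A central cell per layer is needed for the dome the
trophectoderm rests on, which is why the builder uses a 3x3 grid rather
than a ring.

`build_te_monolayer()` drapes a 5x5 sheet of cuboidal cells conformally
over the measured upper surface of the rosette, apical faces inward, and
establishes TE-EPI adhesion.  Draping (rather than a flat sheet) gives
contact across the whole dome at step 0, which is what makes the interface
metrics meaningful from the start.

The default implantation schedule is: step 0, all TE cells retarget from
cuboidal to columnar with the apical ring tapered to half the basal radius
(elongation with a smaller apical surface); steps 3000–6000, the interior
3x3 cells of the TE sheet constrict apically with the step profile
(interior $d = R$, boundary $d = 0$), ramped linearly so that single-cell
constriction progresses gradually rather than as one jump; step 4000,
lumenogenesis (where enabled); step 6000, TE-EPI detachment (in the
detachment variant, which then runs to step 9000).

## Metrics

All evaluation metrics are slice-based scalars, measured in the
mid-sagittal plane (slab half-width $0.5 R$ about the epiblast centre):

* **Interface curvature $\theta$** — the angle at the interface polyline's
  arc-length midpoint subtended by its endpoints; flat interface
  $\theta = 180°$.
* **Interface length $L$, diameter $D$, ratio $L/D$** — arc length,
  endpoint distance and their ratio ($\ge 1$; straight interface 1).
* The interface itself is the set of epiblast membrane particles covered
  by the trophectoderm at the initial stage, tracked as material points
  for the whole run (also after detachment), ordered by polar angle about
  the epiblast centre of mass.
* **Pushing distance** — displacement towards the maternal side (−z) of
  the lowest epiblast particle, the epiblast centre of mass, and the
  population centre of mass, relative to the initial stage.
* **Lumen volume** — the star-shaped cavity around the lumen source,
  estimated on 32 equal-solid-angle direction bins as
  $\sum r_{max}^3 \Delta\Omega / 3$ (empty bins use the mean radius);
  exact for spherical point sets.  A convex-hull volume would be the
  alternative; the radial estimator is used because the cavity is
  star-shaped around the source in every regime the scenarios produce,
  and it needs no geometry library.
* **Fitness $M$** — for trophectoderm-stiffness sweeps, the normalised
  combination of final $\theta$, $L/D$ and pushing distance against the
  sweep's own optima; $M \in [0, 1]$, small where all three are near
  optimal.

## Stiffness calibration

`stress_strain_protocol()` measures a single cell's emergent stiffness:
ten total force magnitudes linearly spaced in $[0, 0.5 J]$ are split
equally over the apical and basal face particles (equal and opposite,
tensile by default), the dynamics are relaxed to equilibrium per load
(energy change below $10^{-8}$ per step over 100 consecutive steps), and
the Young modulus $Y$ is the fitted slope of stress $\sigma = F/S$ against
strain $\epsilon = \Delta L / L_0$, with $S$ the undeformed face area and
$L$ the apico-basal height.  The force schedule scales with $J$, which
keeps strains small ($\sim 0.02$, where the fit correlation exceeds 0.999)
and makes the scaling $Y(cJ) = c\,Y(J)$ exact at convergence.  Larger
target strains leave the linear regime visibly: the Morse network stiffens
exponentially under tension.

Because every spring has stiffness $2 J \rho^2$ at its equilibrium length
and a closed 34-particle triangulation fixes the edge count at
$3V - 6 = 96$ (plus 34 cytoskeleton springs), the *absolute* scale of $Y$
is an emergent property of the mesh layout: for the 34-vertex columnar
cell it is $\approx 36 J$, for the 42-vertex square-basis cell
$\approx 21 J$ (softer: one more ring in series axially and a larger face
area).  Comparative statements — $Y$ increasing with $J$, exact
linearity in $J$, independence from friction above the stability
threshold, ordering between mesh refinements at equal $J$ — are the
robust outputs of the protocol; absolute values should be read as
mesh-specific.

`sweep_friction_ratio()` repeats the protocol while varying
$\lambda_\chi$ at fixed $\lambda_{med}$.  Failed runs (non-convergent or
non-monotone stress-strain response) are data, flagged as *discontinuous*,
and the critical ratio is localised by bisection.

`sweep_jte()` runs the implantation scenario without lumenogenesis for a
grid of `J_TE` values at fixed `J_EPI = 2.5` and computes the fitness
$M$.  With a soft trophectoderm the epiblast is barely reshaped; near
matched stiffness the interface flattens into a cup; with a much stiffer
trophectoderm the interface is driven concave — the fitness minimum sits
in the matched-to-slightly-stiffer band.

## What the scenarios do and do not emulate

The builders generate idealised tissues: perfectly regular meshes,
identical cells, a symmetric rosette, no cell division (cell count is
constant over any run), no stochastic motility, no primitive endoderm, no
uterine wall, and no biochemical signalling.  Passing scenario tests
therefore show that the *mechanical* pathway — elongation, positional
apical constriction, adhesion transmission, apical repulsion — suffices
to produce the tissue-level behaviours in this idealised setting; they do
not quantify rates or magnitudes in real embryos, where proliferation,
heterogeneity and noise all contribute.

Known limitations worth keeping in mind:

* There is no excluded-volume force; interpenetration is prevented only
  by adhesion transmission, which is why the adhesion defaults matter.
* With one-to-one pairing the contact zone stores little elastic energy;
  tissue-level stresses are transmitted faithfully but contact mechanics
  is soft compared to models with explicit repulsion.
* During lumenogenesis the inflating cavity also lets the deformed
  rosette relax towards a rounder shape, which can transiently reduce the
  vertical extent of the tissue; the pushing-distance metrics can
  therefore stall or slightly recede around lumen opening even while the
  trophectoderm continues to push.
* Topology is immutable: no remeshing, no cell rearrangement within the
  lattice, no division or extrusion.

## Problem sizes

The shipped defaults — 18 epiblast cells + 25 trophectoderm cells (1505
particles, ~5600 springs), 6000–9000 steps per scenario, 11-point
trophectoderm sweeps, 10-load stress-strain protocols — run in seconds to
a few minutes each on one CPU core; they were chosen as the smallest
configurations that exhibit a closed rosette, an interior-versus-boundary
constriction profile and a draped cap.
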