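---
title: "Modelling choriocapillaris perfusion as a resistor lattice"
author: "chorioflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choriocapillaris perfusion as a resistor lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chorioflux)
```

## The model and its assumptions

The choriocapillaris of the posterior pole is organized in lobules, each fed
by a central terminal arteriole, drained through collector venules running
along the lobule boundary, and emptied at draining venules where lobule
corners meet. `chorioflux` models this bed as a direct-current resistor
network: flow is current, pressure is voltage, vascular resistance is
electric resistance. The simulation is steady-state and linear; it makes no
attempt to model pulsatility, vessel compliance, autoregulation, blood
rheology or absolute flow calibration. All reported quantities are therefore
either raw amperes under the stated sources or — the quantities of interest —
dimensionless percentages of a perfused reference, which are invariant to
rescaling of the sources.

At every free junction Kirchhoff's current law holds,
$\sum_j (V_i - V_j)/R_{ij} = 0$. Fixed-voltage terminals are eliminated by
substitution rather than by penalty conductances: the unknown vector contains
only free nodes, which keeps the system symmetric positive definite and
avoids conditioning artifacts. The assembled sparse system is solved by a
direct factorization (`Matrix::solve`); correctness is defined by the
residual contract below, not by the choice of algorithm, and the test suite
checks the solver against an independent dense implementation on randomized
networks.

## Lattice geometry

Each lobule is a *dual-layered hexagon with a triangulated interior*:

* 1 center node — the anode (feeding terminal arteriole);
* 6 inner-ring nodes at half the circumradius;
* 12 boundary-ring nodes — 6 corners and 6 edge midpoints.

Interior edges (center–inner, inner–inner, inner–corner, inner–midpoint)
are capillaries; the 12 boundary-ring edges are collector venules. This is
the minimal two-layer all-triangle construction consistent with the lobular
anatomy, giving 19 nodes and 42 edges per isolated hexagon. The builder is
parametric in its resistances and sources, and the geometry was validated
against the published influx percentages of the embolism experiments (all
six endpoints reproduce within ±0.5 percentage points), so this construction
is frozen as the default.

Hexagons tile into a flat-top honeycomb addressed by `"col,row"` with odd
columns offset upward (odd-q layout). Shared corners and edge midpoints are
deduplicated by their exact lattice coordinates; a shared collector venule is
one vessel and receives its resistance once. Cathodes occupy *every other
corner*, and because the corner graph of a hexagonal tiling is bipartite the
alternating choice can be made globally consistently: corners whose scaled
x-coordinate is congruent to 4 (mod 6) are draining venules in every hexagon
that meets them. Node positions are used for rendering and for geometric
tests only; they never enter the physics.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `rows`, `cols` | 5 x 5 | hexagons | lattice extent |
| `capillaryResistance` | 16 | ohm | every interior grid edge |
| `diameterRatio` | 1 | — | collector venule / capillary diameter, in [1, 2] |
| `anodeVoltage` | 51 | V | arteriolar pressure (mmHg-equivalent) |
| `cathodeVoltage` | 23 | V | venous pressure (mmHg-equivalent) |
| solver `tolerance` | 1e-9 | A | max admissible KCL residual |

Boundary (collector venule) resistance follows Poiseuille's law,
$R_b = R_c / d^4$: the physiological ratio range $d \in [1, 2]$ maps onto
16 down to 1 ohm. The `"figure6"` preset (50 V / 10 V sources) ships as an
alternative; percentages are ratio-based and insensitive to it at matched
geometry. The 1e-9 A residual tolerance is several orders below the smallest
reported effect (a 0.04% influx ratio corresponds to ~1e-3 A here).

## Experiments and metrics

Embolism is modelled by demoting an anode to a passive junction: the fixed
voltage is removed but the wiring kept, since an embolized arteriole stump
remains a connected vessel. (Deleting the node instead is possible by
constructing a custom network, but is not the default.)

**Influx** of a lobule is the sum of positive currents entering its interior
node set (center + inner ring) across boundary-to-interior edges, plus the
anode injection when connected. Boundary nodes are excluded from the set so
venule throughflow along the boundary is not counted. In a fully perfused
lattice no current enters any lobule's interior from outside (the test suite
asserts this to below 1e-6 of the anode current) — the end-arterial
behaviour — so influx reduces to the anode injection there.

**Reference convention.** Percentages are computed against the *same-index
hexagon of a fully connected twin lattice* under the identical
configuration, which isolates the effect of the perturbation from edge
effects and from flow spillover in the perturbed lattice. The alternative —
normalizing by the adjacent connected lobules in the same solution — is
reported alongside in `hexMetrics()` as `ratio_adjacent_pct`.

**Embolic order.** Disconnected lobules are classified by hexagon-graph
distance (shared-boundary-edge adjacency) from the connected set: distance 1
is first order, 2 second order, beyond that "deeper". Contact through a
single shared corner does not count as adjacency. Note that on this
honeycomb the corner-most hexagon of a 3 x 3 corner block is at distance 3
(deeper), not second order: a corner hexagon has only two or three
neighbours and they all lie inside the block.

**Default sector.** The sectorial-occlusion experiment defaults to the 3 x 3
block in the upper-left corner (`defaultSector()`, columns 0–2, top three
rows). Because the odd-column offset breaks the equivalence of the four
corners, the four possible corner blocks give slightly different order-mean
percentages (first-order means ranging roughly 17.3–19.0% at 16 ohm); the
upper-left block is the one whose means match the published endpoint values
for both orders at both boundary resistances, and it is frozen as the
default. Any explicit hexagon list can be supplied instead.

```{r sector}
cfg <- LatticeConfig()
ex <- runExperiment(cfg, sectorDisconnect(defaultSector(cfg)))
aggregate(ratio_pct ~ order, ex$metrics, mean)
```

## Numerical choices

* **Sign convention:** currents are stored per edge, positive from the
  byte-order-lower node id to the higher; flow direction derives from the
  sign. This is deterministic and locale-independent.
* **Parallel edges** are forbidden by the network validity check; the mesh
  builder never produces them. Zero or negative resistances are rejected.
* **Degenerate inputs:** a network where every node is fixed has nothing to
  solve and `assembleSystem()` refuses it; the KCL residual of such a
  network is 0 by convention. A disconnected network is refused with the
  unreachable component named. Disconnecting *all* anodes leaves the
  cathodes anchoring the system: it solves to a uniform potential with zero
  current everywhere.
* **Determinism:** identical configuration and scenario give bit-identical
  metric tables. Randomized scenario generation (`sampleScenario`) seeds a
  local RNG and restores the caller's RNG state; segmental sectors grow by
  breadth-first accretion from a seeded corner with ties broken by id order.
* **Reporting precision:** tables retain full double precision;
  `formatPct()` applies the one-decimal (two below 0.1%) display convention
  only at the reporting layer.
* **Problem sizes:** the default experiments solve 339-node systems in
  milliseconds; the property suite uses 100 random networks of 5–30 nodes
  against a dense oracle and a 7 x 7 lattice (643 nodes) for translational
  symmetry, keeping the full test run under a minute on one CPU.

## The synthetic scenario generator

`EmbolismModel()` emulates the two perfusion-defect categories seen
angiographically after experimental fat embolism: *scattered* lobular
defects (each lobule's arteriole embolized independently with probability
`p`) and *segmental* defects (one contiguous sector, as after posterior
ciliary artery occlusion). It emulates only the *spatial pattern* of
disconnection: it does not model embolus size distributions, partial
occlusion, embolism resolution over time, or any correlation structure
between neighbouring arterioles. Passing tests on generated scenarios
therefore demonstrates that the solver and metrics behave correctly across
the perturbation space — not that real emboli distribute this way.

```{r batch}
br <- batchRun(EmbolismModel("scattered", disconnectProbability = 0.3,
                             seed = 1L), cfg, nReplicates = 5)
br$pooled
```

## Known limitations

* Steady-state DC analysis only: no compliance, inertia, pulsatility or
  time-resolved reperfusion.
* The inner-ring count (6) and boundary discretization (12 nodes) are a
  reconstruction; finer internal grids would change absolute currents,
  though the percentage endpoints validated above constrain the choice.
* Absolute flow is uncalibrated by design; only ratios are meaningful.
* The upstream arteriolar tree and large choroidal vessels are not
  modelled; a sector occlusion is represented purely as the loss of its
  terminal arterioles.
* Lattice edges (the 5 x 5 rim) see boundary effects of a few percent in
  anode currents; interior hexagons of a 7 x 7 lattice agree within 1%.
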