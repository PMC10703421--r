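---
title: "mitosim: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitosim: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosim)
```

## The model

`mitosim` simulates the mitochondrial network of a budding yeast mother
cell as a collection of 2D, non-deformable, indivisible particles, each
representing one unit mitochondrion.  Mitochondria in small yeast cells
move mostly along the inner cell cortex, so the domain is a periodic
square whose area equals the surface area of the (spherical) mother cell;
with the default mother volume of 54.04 µm³ the box side is
`L = sqrt(4*pi*r^2) ≈ 8.31` µm.  The unit particle is calibrated to the
mean fragment volume of a fusion-null (Δfzo1) strain (0.12 µm³, radius
0.31 µm as a sphere), and the particle count to the mean total
mitochondrial volume: `floor(6.56 / 0.12) = 54` particles.

Three stochastic processes act on the particles at each 0.1-s timestep:

* **Diffusion.**  Every connected network translates as a rigid body by a
  displacement of fixed length `sqrt(4 * D(v) * dt)` at a uniformly random
  angle, where `D(v)` is a linear function of the network's 3D-equivalent
  volume `v` (particle count × 0.12 µm³).  The squared per-step
  displacement is therefore exactly `4 D dt`, so the mean squared
  displacement of a free particle is `4 D t` by construction — a property
  the test suite uses as a parameter-recovery check.
* **Fusion.**  Two networks whose closest particles are within one
  particle diameter (`2 r_particle`, minimum-image metric) may fuse; on
  success an edge joins the closest particle pair, merging the networks.
* **Fission.**  A network of more than one particle may lose one edge,
  splitting it in two.

Connectivity is a forest by construction — fusion only ever joins two
distinct components and fission removes a single edge — so the number of
networks plus the number of edges always equals 54.  Event probabilities
per step come from volume-dependent linear rate laws (per-second rates
clamped at zero, converted to per-step Bernoulli probabilities), with
separate laws for three conditions: WT, aggregate-free mitochondria in
aggregate-expressing cells (DUMP−), and aggregate-bearing mitochondria
(DUMP+).  Whether a network uses the DUMP+ or DUMP− laws is decided by
whether it contains at least one marked particle; the mark spreads its
behavior to the whole connected structure.

## Run schedule and DUMP seeding

A run starts from 54 singleton particles at uniform positions and
equilibrates for 1800 s under the WT laws, which lets the network
self-organize until the number of discrete structures stabilizes.  At
1800 s, 6 particles (12.2 % of the total volume) are marked as
DUMP-bearing, arranged as `N` clusters: `N` seed particles are drawn, and
flood fill grows each cluster one adjacent particle at a time in
round-robin order.  Any draw in which two clusters would touch is
rejected wholesale and re-sampled (up to 10,000 attempts, after which the
run aborts with a seeding error — this can only happen when the forest
cannot host the requested structure, e.g. 1 cluster of 6 with no network
of 6 particles).  `singlets` mode marks 6 pairwise non-adjacent
particles, which is identical to requesting 6 clusters.

The cluster count is either fixed or drawn per run from a discrete
distribution.  The shipped default emulates steady-state constitutive
aggregate expression, which produces on average 1–2 aggregates per cell:
a geometric distribution with success probability 2/3 (mean 1.5),
truncated to 1–6 and renormalized.  This default is a synthetic
placeholder — the in-vivo cluster-count distribution is not published as
a table — and should be replaced through `seeding_spec()` when a measured
distribution is available.

After seeding, the run continues for 5400 s (one average budding cycle)
under a configurable combination of laws (`sim_config()`): WT or
DUMP−/DUMP+ fission/fusion, WT or DUMP−/DUMP+ diffusion, and the fission
placement bias.

## Biased fission

Without bias, the removed edge is uniform over all edges of the splitting
network.  With `placement_mode = "biased"` and fraction `f`, each fission
event is, with probability `f`, restricted to *boundary* edges — edges
joining a marked and an unmarked particle; with probability `1 - f` it
falls back to the uniform rule (so a uniformly-drawn cut may land between
two marked particles).  In `adjacent` mode the restricted cut lands one
hop outside the marked set (between a particle at graph distance 1 from
the marks and one at distance 2).

Two edge cases are resolved deliberately:

* A network that contains marked particles but has no eligible edge (an
  all-marked fragment) **skips** the fission event rather than falling
  back to a uniform cut.  Aggregate-biased fission is only defined at the
  aggregate boundary, and a uniform fallback would cut marked–marked
  edges and split clusters, which would violate the model's central
  monotonicity property (under `f = 1` the number of DUMP clusters can
  never increase: biased fission never cuts inside a cluster, and fusion
  can only merge clusters).
* A fully unmarked network always splits at a uniform random edge — the
  bias has nothing to act on.

## Inheritance algorithm

Inheritance is evaluated without modifying the state, mimicking the
observed two-step extrusion of a mitochondrial branch into the bud:

1. the largest network (most particles) is identified;
2. the tip of its longest branch is found — formalized as an endpoint of
   a tree-diameter path in hop count, since all bonds have the same
   physical length — and 15 particles (`floor(1.83 / 0.12)`) are
   collected from the tip by breadth-first search.  A smaller network is
   inherited whole.

If any inherited particle is marked, the bud has inherited a DUMP — a
failure of asymmetric retention.  All ties (largest network, diameter
endpoint, BFS frontier order) are broken uniformly at random from the
run's RNG stream: the text of the underlying procedure specifies no
tie-break, and any deterministic order would bias inheritance toward
particle-id artifacts.  The diameter endpoint is found by the double
breadth-first sweep, which is exact on trees; the test suite checks it
against brute-force all-pairs distances on random trees up to 54 nodes.

## Parameters

All defaults live in `sim_params()` and mirror the calibrated
measurements:

| parameter | default | units | meaning |
|---|---|---|---|
| `unit_mito_volume` | 0.12 | µm³ | unit mitochondrion (Δfzo1 fragment mean) |
| `mother_cell_volume` | 54.04 | µm³ | mother cell; sets the box side 8.31 µm |
| `total_mito_volume` | 6.56 | µm³ | sets `n_total = 54` |
| `bud_mito_volume` | 1.83 | µm³ | sets `n_inherit = 15` |
| `dump_occupancy` | 0.122 | — | sets `n_dump = 6` |
| `dt_sim` | 0.1 | s | simulation step |
| `dt_expt` | 10 | s | imaging frame interval (snapshots, downsampling) |
| `t_equil`, `t_eval` | 1800, 5400 | s | run schedule |

The nine rate laws (fission, fusion, diffusion × WT, DUMP−, DUMP+) are
least-squares slope/intercept pairs against 3D-equivalent volume; they are
inputs to this package, not re-fit here.  Derived counts use the floor of
the volume ratios — all three calibrated printed values equal the floor.

## Numerical choices

* **Per-step probabilities** use the capped linear form `min(1, rate*dt)`;
  at the calibrated rates and `dt = 0.1` s it differs from
  `1 - exp(-rate*dt)` by under 0.1 %.  The exponential form is available
  via `prob_model = "exact"`.
* **Negative raw rates** (linear laws go negative at small volumes) are
  clamped to zero; diffusion is clamped at a floor of 1e-12 µm²/s so step
  lengths stay defined.
* **Operation order** within a step is diffuse → fusions → fissions,
  fixed.  Simultaneous fusion contacts are processed in random order with
  component membership recomputed after each success, which keeps the
  forest acyclic; at most one fission per network per step.
* **The fusion trial rate for a contacting pair** is the mean of each
  partner's own fusion law at its volume: the experimental rate was
  measured per pre-fusion mitochondrion and the pair event must be
  symmetric in the partners.
* **Distances** use the minimum-image convention everywhere; trajectories
  are unwrapped before MSD analysis (per-step displacements are far below
  half the box, so unwrapping is unambiguous).
* **No post-fission displacement** separates fragments; they may re-fuse
  in later steps while still in contact.
* **Event downsampling** to the 10-s imaging cadence assigns each event to
  its nearest frame and collapses events of one type on the same network
  lineage within one frame, emulating the loss of event resolution at
  longer frame intervals.
* **RNG**: one seeded stream per run (R's generator drives both the R and
  C++ halves), so every run is exactly reproducible from its seed.

## What the simulation does and does not emulate

The generator reproduces the *statistical* conditions of the calibrated
system: particle counts, box geometry, volume-dependent rates, the run
schedule, and cluster-structured aggregate seeding.  It does not model
tubule geometry or bending, deformable or three-dimensional mitochondria,
lattice-like hyperfused morphologies (fission-null mutants), intra-matrix
aggregate diffusion, membrane potential, or active transport through the
bud neck; inheritance is abstracted to the two-step selection above.
Passing tests therefore support the remodeling-and-selection logic of the
model, not a claim that real mitochondria are rigid disks.

MSD analysis exposes both conventions: `slope` fits `MSD = D t` (the
convention used for the calibrated coefficients) and `diffusion_2d =
slope / 4` is the physical 2D coefficient; for a free particle the
engine's step rule makes the slope exactly `4 D` in expectation.  The
discrepancy between the two conventions is deliberate and documented
rather than silently corrected.

## Problem sizes used for verification

The package's own verification scripts and tests use: 140 replicate runs
for the baseline (bias-off) inheritance probability; 50 replicates per
fraction for the bias sweep over {0, 0.2, 0.4, 0.5, 0.6, 0.8, 1.0}; 1000
replicate free-particle tracks for diffusion recovery; 10,000 forced
fissions for placement-distribution checks; and 25 replicates per cluster
count for the cluster-count trend.  These sizes give Monte-Carlo standard
errors of a few percentage points on the reported probabilities while
keeping a full verification pass on one CPU in the tens of minutes.

## Known limitations

* The default cluster-count distribution is a documented placeholder, not
  a measurement; conclusions sensitive to the seeded cluster count should
  be checked against a measured distribution.
* The forest representation cannot express ring or lattice topologies, so
  hyperfused mutant morphologies are out of scope.
* Fusion placement always joins the closest particle pair; preferential
  tip-to-tip fusion observed in vivo is not modeled, which may make
  simulated attachment geometry slightly more uniform than reality.
* With 54 particles in an 8.31-µm box the particle area fraction is
  appreciable (~23 %), so contact opportunities — and hence effective
  fusion frequency — depend on the excluded-volume approximation of
  treating particles as freely overlapping disks.
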