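---
title: "Steered tip molecular dynamics: model, integrator and design notes"
author: "steermd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steered tip molecular dynamics: model, integrator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steermd)
```

## The problem

Scanning-probe manipulation experiments grab a single organic molecule with a
metal tip and drag or lift it across a metal surface. The junction geometry —
binding site, bond character, molecular conformation — is exactly what
electronic-structure transport models need as input and exactly what the
experiment cannot see. A classical molecular-dynamics engine that follows the
same steering commands as the instrument, fast enough to keep up with the
operator, acts as an "eye" on the junction: it shows a plausible atomistic
configuration for every point of the manipulation.

`steermd` implements such an engine for a three-component system: an fcc(111)
metal slab, a pyramidal metal tip whose top layer follows external x,y,z
commands, and a planar covalently bonded molecule (the bundled example is
1,4-bis(4-pyridyl)benzene, C16H12N2, with a pyridyl nitrogen at each end).

## Force model

All quantities are in angstrom / amu / eV; the derived time unit is
`sqrt(amu Å² / eV)` ≈ 10.1805 fs, so `F = ma` needs no conversion factors
(`fs_to_tu()` / `tu_to_fs()` convert step sizes).

* **Intramolecular terms.** Covalent bonds are harmonic springs
  `V = ½ k_b (r − r₀)²`; bond angles are harmonic in the angle,
  `V = ½ k_θ (θ − θ₀)²`; torsions use the periodic form
  `V = k_φ (1 + cos(mφ − φ₀))`. The interaction tuples are enumerated once
  from the molecular graph (`bonded_tuples()`): one angle per pair of bonds
  sharing a central atom, one proper dihedral per three-bond path. With at
  most *n* bonds per atom, no atom participates in more than `n` bond terms,
  `(3/2)n(n−1)` angle terms and `2n(n−1)²` dihedral terms
  (`max_counts_per_atom()`); these bounds — which size the fixed-width
  per-atom work lists of a parallel force layout — are reproduced exactly by
  exhaustive enumeration over all connected graphs with up to 8 atoms
  (`observed_count_maxima()`), where the cube graph attains the n = 3 bound
  and K4,4 the n = 4 bound.
* **Metal–molecule terms.** Non-anchoring species (C, H) interact with metal
  atoms through 12-6 Lennard-Jones; anchoring species (N, S) through a Morse
  potential `V = D[(1 − e^{−a(r−r_e)})² − 1]`, the stronger, bond-like
  attachment through which the tip grips the molecule. A per-(species, role)
  affinity table scales the well depth; by default the tip binds N three
  times more strongly than the substrate, a pair-potential surrogate for the
  enhanced reactivity of the low-coordinated apex atom.
* **Metal–metal term.** Substrate cohesion uses a second-moment
  (Gupta-style) many-body potential with Cleri–Rosato gold constants. Tip
  atoms are instead tethered to anchor sites by harmonic restraints
  (`k_tip = 5 eV/Å²`); the handle (top) layer's anchors are what steering
  moves. Consequence, stated as a limitation: the tip has no metallic
  interaction with the substrate, so driving the apex into the surface is
  not penalized by the model — steer accordingly.
* **Cutoffs.** All pair terms share the 6 Å cutoff that also sets the cell
  edge of the neighbor grid. LJ/Morse use shifted-force truncation, so both
  the energy and the radial force go continuously to zero at the cutoff; the
  many-body metal term uses a C¹ cosine switching function over the last
  0.5 Å instead, because a force-shift is not well defined through the
  embedding square root. Truncation is therefore never a source of impulsive
  noise; dissipation is owned by the thermostat.

Every parameter lives in `default_forcefield()` with a provenance marker:
`"method"` for the few structural constants fixed by the algorithm (32-atom
cell cap, 20-step refresh, planar degree cap 3) and `"package"` for all
numerical values, which are representative literature-style defaults, not
fitted constants, and are meant to be overridden when calibrating against a
specific experiment.

## Neighbor search

Pair candidates come from a two-dimensional cell grid over x,y with cell
edge = cutoff + skin (0.3 Å): all neighbors within the cutoff of an atom are
guaranteed to lie in its own or the eight surrounding cells, which turns the
O(N²) pair search into O(N) at fixed density (`bench_pairs()` measures
log-log slopes of 1.08 for the cell list vs 2.00 for brute force over
N = 507…8112). Cells are unbounded in z and the outermost ring is unbounded
outward, so every finite position maps to a cell. An atom exactly on a cell
boundary belongs to the higher-index cell (floor convention), making tests
exact. Cell occupancy is capped at 32 per role class (metal and molecule
atoms keep separate sublists, mirroring the separate molecule cell index of
the original layout); atoms beyond the cap are excluded from pair generation
but counted — `get_counters()` always reports the overflow, which is zero
for all default builds. The grid is refreshed every 20 cycles; the skin
margin keeps the stale-grid pair set exact under bounded drift, which the
suite verifies against the brute-force oracle.

## Integration

The engine must resolve C–H vibrations (~11 fs period) while the operator
steers heavy metal atoms; a single shared time step would either break the
molecule or be needlessly small for gold. The multi-time-step cycle splits
the system:

* **gold-only subsystem** — all metal atoms, advanced one large step
  Δt = 5 fs by velocity Verlet under metal-side forces, with the molecule as
  a static field acting on non-interface metal atoms;
* **extended-molecule subsystem** — the molecule plus the *interface* metal
  atoms (those within 1.2 × cutoff of an anchoring atom), advanced α = 20
  small steps δt = Δt/α = 0.25 fs; interface atoms here start each cycle at
  zero velocity and feel only molecule-side forces.

At cycle end, interface displacements and velocity increments from the two
subsystems are added; molecule atoms take the extended result and all other
metal atoms the gold result. This routing integrates every force term
exactly once — the two subsystem force fields sum identically to the full
assembly, which the suite asserts — and makes the α = 1, Δt = δt limit agree
with single-timescale Verlet to O(dt³) per step (measured: ~10⁻⁶ Å RMSD
over 100 steps; exact agreement is impossible for any splitting scheme
because the closing half-kick sees subsystem-local positions). At the
defaults, 100 cycles on a 300-atom slab plus molecule stay within 0.01 Å
molecule RMSD of an all-atoms-at-δt reference.

A constant-friction thermostat `v ← (1 − γ dt) v` (first-order
discretization of a −γmv drag) removes the energy pumped in by steering;
it applies to all mobile atoms by default and is configurable per subsystem
because the original description does not say which part is damped. γ
defaults to 10⁻³ fs⁻¹ (kinetic-energy decay ~0.5 ps); manipulation runs use
5·10⁻³ fs⁻¹ so the system re-equilibrates within ~100 cycles of any tip
move. The per-cycle ordering is kick–drift–kick, then damp. With γ = 0 the
integrator is symplectic Verlet: over 10⁴ small steps the vacuum molecule
shows a secular energy drift of ~10⁻⁶ relative (we report drift as the
difference of mean energy between the last and first 10% of the run — the
bounded ~10⁻³ Verlet energy oscillation is not drift and is asserted
separately).

Frozen atoms (the bottom substrate layer by default) are excluded from
integration everywhere. NaN anywhere in the state aborts immediately with a
step dump rather than propagating.

## Steering

Tip commands are timed (x, y, z) waypoints in units of cycles
(`tip_trajectory()`, hold or linear interpolation), polled every
`k_cycles = 10` cycles (5 for manipulation runs); between polls the handle
anchors keep their fixed intra-layer offsets around the commanded center.
The quasi-static guard clamps anchor motion to `max_step = 0.02 Å` per cycle
and counts violations — steering faster than the system can relax makes the
simulation a poor witness of the experiment, which is the regime the
relaxation-time estimator (`estimate_relaxation_time()`) is meant to flag. A
live-input source is just a trajectory whose waypoints arrive at poll time;
no device code is included.

The packaged scenario (`run_manipulation()`) replays the canonical
manipulation: relax (150 cycles), approach the apex to 2.4 Å above the
molecule plane, hold 100 cycles while the Au–N anchoring bond forms, drag
3 Å laterally, lift 16 Å. Conditions were fixed from geometry: the molecule
is ~12.4 Å long, so a 16 Å lift is what it takes for the trailing end to
clear 2 Å above the surface once the molecule hangs vertically; the steering
speed 0.01 Å/cycle is half the guard. Success criteria: every molecule atom
ends > 2 Å above the surface with every bond within 20% of its rest length
(molecule lifted intact), and the N–tip distance stays within the anchoring
cutoff throughout drag and lift. The pull curve (commanded height, minimum
anchor distance, vertical handle force) is recorded per cycle.

## Verification strategy

Analytic forces are the package's own; every one of them is checked against
central-difference gradients of its energy on randomized geometries (bond,
angle 10⁻⁶ relative; dihedral 10⁻⁵; pair potentials 10⁻⁶; many-body metal
term 10⁻⁶ on 20-atom clusters), alongside exact invariances: zero net force
and torque per bonded term, translation invariance, rotational covariance,
Newton's third law pairwise. The cell-list path must reproduce the
brute-force all-pairs assembly bitwise (identical canonical pair order) on
overflow-free systems. The graph enumerator is itself validated against a
labeled brute-force enumeration over all edge subsets (with explicit
permutation dedup) for up to 5 vertices, independently of the igraph
canonicalization it uses. The dimer equilibrium of the metal potential is
checked against a one-dimensional root find on the pair energy.

Problem sizes in the shipped suite — 8-atom graph enumeration, 507-atom
oracle-equivalence system, 100-cycle MTS comparisons, 10⁴-step conservation
runs, N ≤ 8112 scaling series, one full manipulation — were chosen so each
check exercises the claim it tests at a few minutes of single-core runtime;
all of them scale up by changing one argument.

## What the generated systems do and do not emulate

The builders produce idealized conditions: a defect-free ABC-stacked slab, a
perfectly planar idealized-hexagon molecule that is an exact mechanical
equilibrium of the default bonded parameters, a symmetric pyramid tip, zero
temperature (thermostat only, no thermal noise). Passing tests therefore
demonstrate the correctness of the machinery — enumeration, forces,
neighbor search, integration, steering — under controlled conditions; they
do not validate the default parameters against any real junction. Real
systems add surface reconstruction, per-species adsorption differences,
thermal fluctuations, bond formation/breaking chemistry beyond the Morse
well, and electronic effects, all outside this model. The affinity contrast
that makes the lift succeed is imposed, not emergent; with equal tip and
surface affinities the same script may leave the molecule on the surface.

## Numerical choices and degenerate inputs

Collinear angle arms and degenerate dihedral frames are evaluated with an
ε-regularized norm (10⁻¹²) and counted (`degenerate_geometry`), never
returned as NaN. Coincident bonded atoms and missing tip anchors are hard
errors. Accumulation of per-tuple forces uses a fixed, sorted tuple order,
so single-threaded runs are bit-reproducible; `dump_effective_config()`
plus the seed reproduces a run exactly. Steering rate violations are
clamped, warned about and counted rather than honored.

## Known limitations

* Tip–substrate and tip–tip metallic cohesion is absent (harmonic anchors
  only): fine for manipulation above the surface, wrong for indentation.
* The 2D cell grid assumes a laterally extended, vertically thin system; a
  tall 3D structure would need a 3D grid (documented extension point).
* Pair-potential anchoring cannot capture coordination-dependent metal
  reactivity; the affinity table is a stand-in.
* No electrostatics, polarization or chemistry; bond topology is fixed for
  the whole run.
* Wall-clock "real-time" performance is hardware-bound and deliberately out
  of scope; the package reports hardware-independent operation counts
  instead.
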