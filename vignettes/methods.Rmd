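---
title: "Modelling surface-aged MoS2 nanosheet insertion into lipid membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling surface-aged MoS2 nanosheet insertion into lipid membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetmem)
```

## The scientific question

Freshly exfoliated MoS2 nanosheets adsorb airborne hydrocarbons within
hours; the aged surface is markedly more hydrophobic (water contact angle
rising from about 69 to about 90 degrees). In CHARMM-like force fields
this aging is captured by a single parameter: the Lennard-Jones well
depth of the sulfur site, eps_S, which falls from 1.6744 kJ/mol (fresh)
to 1.0450 kJ/mol (aged) along an accurately linear function of the
contact angle. `sheetmem` provides a desk-scale computational chain for
asking how that one scalar changes the thermodynamics and kinetics of
nanosheet insertion into lipid bilayers: sheet construction and
parameterization, a coarse stochastic insertion simulator, umbrella
sampling with a from-scratch WHAM estimator, and the trajectory
statistics membrane-insertion studies report (contacts, bound waters,
CoM depth, energy decomposition, chain order, thickness, insertion
times).

Everything uses one unit system: nm, ps, kJ/mol, K, elementary charges,
with `KB = 0.0083144621` kJ/mol/K.

## The nanosheet model

`build_triangular_nanosheet()` cuts a three-layer S-Mo-S sheet from the
2H-MoS2 lattice as an equilateral triangle (reference side length
2.89 nm), one vertex on the +y axis, sheet normal along +z. The lattice
constants are not part of the aging parameterization and we take the
standard crystallographic values: in-plane a = 0.316 nm, Mo-to-S-plane
offset 0.156 nm (both overridable through the `lattice` config block).

Two choices were genuinely open:

* **Cut registry and boundary rule.** A sulfur column sits at the
  triangle centroid and the cut keeps any site within half an in-plane
  Mo-S bond projection (a/(2 sqrt(3)) ~ 0.091 nm) of the nominal
  triangle, so edge unit cells are kept whole rather than split. With
  this rule the trimmed sheet retains its corner atoms and the maximal
  vertex-to-vertex extent stays within half a lattice spacing of the
  nominal side length.
* **Neutralization.** A triangular cut need not be stoichiometric.
  Rather than rescaling the tabulated charges (+0.76 e Mo, -0.38 e S),
  excess atoms of the over-represented species are trimmed from the edge
  inward (farthest from the centroid first, ties broken
  lexicographically) until Mo:S is exactly 1:2. The result is neutral to
  machine precision and fully deterministic. Edge sulfur atoms keep the
  uniform tabulated charge; no edge-specific reparameterization is
  attempted.

`eps_from_wca()` is the straight line through the two anchor states
(69 deg, 1.6744) and (90 deg, 1.0450); outside that bracket it
extrapolates with a warning.

## The coarse simulator

Atomistic molecular dynamics is out of scope by design; the simulator's
job is to generate trajectories with the statistical structure the
analyses assume, at seconds of CPU.

The sheet is a rigid body with four overdamped-Langevin degrees of
freedom (CoM x, y, z and tilt), integrated with the Euler-Maruyama
update `x <- x + dt F / (gamma m) + noise`, noise variance
`2 kB T dt / (gamma m)`. The membrane enters in two forms:

* **Implicit membrane** (`implicit_membrane()`): a smooth 1-D profile
  along the normal - exactly zero in bulk, a small interfacial barrier
  (default 1.5 kJ/mol) at |z| = half thickness (default 2.0 nm), and an
  attractive well across the core whose depth scales linearly with
  eps_S: `U_t = -6 eps_S` (about -10.0 kJ/mol fresh, -6.3 kJ/mol aged,
  i.e. ~4 kT vs ~2.5 kT at 300 K). The proportionality constant 6 was
  fixed once so that both surfaces insert spontaneously on desk-scale
  runs while umbrella windows can still sample both sides of the
  interface. An orientational term (default 5 kJ/mol) favours the
  sheet-normal perpendicular to the membrane normal inside the core,
  the pose inserted sheets adopt. The envelope uses a C2 quintic
  smoothstep and a compactly supported bump, so the midplane energy is
  exactly `U_t` and the bulk energy exactly zero.
* **Bead membrane** (`build_coarse_membrane()`): two leaflets of
  head + chain-bead lipids on a grid, built with all chains aligned
  (S_chain = 1), head planes at +/-1.9 nm. It exists so that contact,
  thickness and chain-order analyses have explicit particles.
  `relax_membrane()` lets it respond to an inserted sheet: beads are
  bonded along each lipid, softly tethered to their lattice sites
  (deliberately softer in z so the bilayer can swell), repelled by
  sheet atoms through an exponential wall, and optionally attracted to
  the sheet via a longer-ranged term applied to tail beads whose
  amplitude scales with eps_S (`20 eps_S` kJ/mol in the ordering
  tests) - the coarse transcription of "the fresh surface binds lipid
  tails more strongly". At much stronger coupling the tails wrap the
  sheet and the order parameter is no longer monotone in eps_S, so the
  amplitude was fixed in the linear-response regime. Structural
  observables are read from the time-averaged second half of the
  relaxation, which separates the mechanical deformation from bead-level
  thermal noise.

`scripted_scenario()` produces deterministic trajectories of the
qualitative insertion stages (approach, optional face-to-face
preorganization plateau, vertex-first insertion, dehydration) with
ground truth embedded by an independent brute-force pass, so every
analysis function can be tested against exact expected values.

What the generator does **not** emulate: explicit water dynamics (the
bath is static), lipid chemistry beyond head/tail labels, electrostatics
beyond truncated Coulomb, pressure coupling, and the absolute magnitudes
of atomistic observables. Green tests therefore certify the estimators
and the fresh-vs-aged *orderings*, not atomistic numbers.

## Umbrella sampling and WHAM

The reaction coordinate d is the signed sheet-membrane CoM separation
along the membrane normal, with the bilayer midplane as reference. The
restraint is the linear force `F = k (d - d0)` with the protocol force
constant k = 2000 kJ/mol/nm^2; the corresponding bias energy is taken in
the standard harmonic convention `k (d - d0)^2 / 2` (the force form
alone is ambiguous up to a factor-of-two convention). The default ladder
reconstructs the published protocol - 0.1 nm spacing, 50 windows - as
0 to 4.9 nm; the endpoints are not printed anywhere authoritative, so
this reconstruction is config-overridable.

`wham()` is a from-scratch self-consistent WHAM solver in log space,
iterating the window shifts f_i to `tol` (default 1e-7 kJ/mol, max 1e5
sweeps) over a 200-bin histogram by default, with plain bootstrap
(50 resamples) for per-bin uncertainty. The PMF is zeroed on the bulk
region, defined as the outermost 10 percent of the sampled range.
`pmf_minimum()` refines the minimum parabolically and ignores bins
holding fewer than 2 percent of the best-sampled bin's count - a
minimum supported by a handful of correlated tail excursions is
histogram noise, not a well.

Numerical choices that matter in practice:

* The Euler-Maruyama stationary distribution carries an O(dt) variance
  bias of about `1/(1 - mu k dt / 2)`; window time steps default to
  values keeping that under about 1 percent (dt = 1e-5 ps at k = 2000).
* For well-depth *recovery* the package samples ladders with a softer
  restraint (k = 100) than the protocol constant, because at desk-scale
  sampling budgets the f_i random walk across 2.8-sigma-spaced stiff
  windows dominates the depth error; the protocol k remains the
  default everywhere the protocol is being reproduced rather than
  inverted. Recovery runs use 0.15 nm spacing over 0-3.3 nm, 20 ps of
  production per window, and 60 bins; under those budgets the known
  implicit-membrane depth is recovered within a few percent.
* All windows of a ladder advance together through one vectorized
  integration loop (one RNG stream), which is statistically equivalent
  to independent runs and an order of magnitude faster in R.

## Trajectory statistics

All distance criteria are atom-centre to atom-centre with minimum-image
wrapping in the periodic directions (x, y; the normal is open):

* contacts: a membrane atom is in contact if any sheet atom is
  *strictly* closer than 0.5 nm (the 5 Angstrom criterion); head/tail
  splits partition the same count;
* bound waters: oxygen within (inclusive) 0.35 nm of the nearest sheet
  atom centre, the simplest reading of "within 3.5 Angstrom of the
  surface";
* chain order: `S_chain = <(3 cos^2 theta - 1)/2>` with theta between
  the first-to-last chain-bead vector and the membrane normal. The
  formula gives -0.5 (not +0.5) for chains perpendicular to the normal;
  prose descriptions sometimes label the perpendicular case "0.5", but
  the implementation follows the formula exactly;
* membrane thickness: inter-head-plane separation (the phosphate-plane
  convention), computable globally or restricted to lipids within
  1.0 nm of the sheet - published usage is ambiguous between the two,
  so both are exposed;
* insertion time: first crossing of the sheet CoM below the proximal
  head plane that is sustained for 5 percent of the trajectory length -
  the sustain rule makes an otherwise eyeballed estimator deterministic;
* energy decomposition: pairwise shifted Lennard-Jones and truncated
  Coulomb at the 1.2 nm protocol cutoff - deliberately the simulator's
  truncation scheme, not particle-mesh electrostatics.

The neighbour-grid contact search is cross-checked against an O(N^2)
brute-force oracle, and scripted-scenario series against the
generator's embedded truth, in the test suite.

## Problem sizes and runtimes

The shipped defaults are sized for a single CPU: ladder sampling runs
use 10-40 ps of overdamped time per window (minutes for a full 50-window
protocol ladder), insertion runs 15-20 ps (about a second), bead
relaxations 4000 steps over ~300 beads (a few seconds), and the
scripted scenarios 61 frames. The fresh-vs-aged comparisons use five
seed pairs with common random numbers per pair, which removes most
realization noise from the paired contrast.

## Known limitations

* The coarse model shares no energy scale with atomistic force fields;
  only signs and orderings transfer. The published atomistic magnitudes
  (interaction energies near -1000 kJ/mol, minima at 0.8-1.0 nm,
  insertion times of tens of ns) are out of scope.
* Ions are omitted: the published solvent composition is internally
  inconsistent (0.15 M vs the stated ion and water counts) and the
  coarse model has no electrostatic screening to represent.
* The bead membrane has no lipid-lipid cohesion; its elastic response
  is set by tethers and bonds, so absolute thickness changes are
  model-scale, not predictions.
* PMF bootstrap errors are plain resampling errors; they understate
  autocorrelation within a window by roughly the effective-sample
  deficit of the sampler.
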