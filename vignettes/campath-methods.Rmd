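---
title: "Methods: minimum free energy paths and permeation statistics in campath"
author: "campath authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimum free energy paths and permeation statistics in campath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campath)
```

# Scope

campath analyses multi-ion permeation through narrow, highly selective
ion channels of the CaV type. Its inputs are the artefacts such studies
produce -- gridded potentials of mean force (PMFs) over ion z-positions,
driven permeation trajectories, selectivity-filter coordination frames,
and molecular topologies -- and all of them can be generated synthetically
by the package, so the statistical machinery is testable end to end
without molecular dynamics.

# The minimum free energy path search

## Model

On a PMF grid the "resistance" of a path is the integral of exp(E/RT)
along it; the MFEP is the path of least total resistance between two
points. Discretely, each edge between neighbouring nodes u, v contributes

$$ r_{uv} = \tfrac12\left(e^{E_u/RT} + e^{E_v/RT}\right)\,\lVert x_u - x_v\rVert, $$

a trapezoidal rule over the edge. The trapezoidal choice converges
consistently under grid refinement; any alternative quadrature must pass
the same exhaustive-search and low-temperature checks the test suite
applies to this one.

The search proceeds in five steps: (1) every unmasked node is assigned a
*successor*, the lowest-energy node among itself and its neighbours; (2)
nodes that are their own successor are *fixed points* (local minima), and
successor chains partition the grid into attraction basins; (3) basins
sharing adjacent nodes define a coarse-grained (CG) state network; (4)
between the fixed points of every pair of adjacent basins, the
minimum-resistance segment is found by a Dijkstra search over the whole
grid; (5) a second Dijkstra search on the CG network, weighting each edge
by its segment resistance, selects the basin chain, and the segments are
spliced into the final path. Query points snap to the nearest unmasked
node and are represented by their basin's fixed point; the reported path
runs fixed point to fixed point, with an option to prepend/append the
steepest-descent chains from the raw query nodes.

## Numerical choices

* **Log-space costs.** Resistances span hundreds of orders of magnitude
  (at T = 1 K, exp(E/RT) overflows double precision for E above a few
  kJ/mol). All accumulation uses log-sum-exp, so path costs are exact at
  any temperature and the T -> 0 limit reproduces the minimax
  (lowest-barrier) path, which the tests verify against a brute-force
  threshold-percolation oracle.
* **Connectivity.** The default neighbourhood is the full Moore set (all
  3^d - 1 adjacent nodes). Diagonal moves avoid staircase artefacts on
  fine grids; an axis-only mode is available. "Neighbouring" is a
  modelling choice, so it is a parameter, not a constant.
* **Tie-breaking.** Everywhere (successor choice, heap ordering), ties
  resolve to the smallest flat node index, making results deterministic.
  On a flat plateau every node without a strictly lower neighbour becomes
  its own fixed point; this is documented behaviour, not "fixed", since
  any remedy would impose an arbitrary drainage direction.
* **Axes.** Non-periodic by default; periodic axes wrap both neighbour
  generation and edge lengths. Energies are kJ/mol; the axis unit is
  declared once per grid (default angstrom).
* **Reaction coordinate.** Profiles use cumulative arc length normalised
  to [0, 1]; node index would distort mixed axis-diagonal paths.
* **Profile statistics.** The SD across aligned profiles is the
  population SD (divide by n), the natural convention for snapshots of a
  fluctuating PMF rather than independent replicates.

## When the coarse-graining is exact, and when it is not

The CG construction restricts candidate paths to those passing through
the fixed points of intermediate basins. If the start and end basins are
adjacent, the CG answer *is* the full-grid optimum (the direct CG edge
carries exactly the full-grid segment cost). Across intermediate basins
it is exact whenever the optimal path naturally funnels through basin
minima -- the deep-well, smooth-surface regime in which PMFs of ion
channels live (barriers of 10-40 kJ/mol against RT of about 2.6 kJ/mol).
On rough surfaces whose optimal path clips a basin without descending to
its minimum, the CG cost can exceed the full-grid optimum.
`mfep(..., verify = TRUE)` runs the exhaustive search alongside and
records the discrepancy on the result instead of hiding it. The package's
random smooth surface generator (`randomSmoothLandscape()`) draws
Gaussian features with widths of 0.2-0.4 of the domain edge, i.e. every
feature spans many grid cells; in this family the test suite requires
exact agreement between the CG search and full-grid Dijkstra (20 surfaces
in 2D at 30x30, 5 in 3D at 12^3 -- sizes chosen so the exhaustive oracle
remains cheap, not because the method needs small grids).

# Permeation events and conductance

Events are counted by a two-plane state machine with hysteresis: an
inward event completes only when an ion last seen above the upper plane
is next seen below the lower plane, so an ion dithering at one plane is
never double-counted. Periodic-boundary jumps are detected as
|dz| > boxZ/2 between consecutive frames and reset the ion's bookkeeping
rather than counting as crossings. The planes default to the filter
extent plus a 2 A margin and are configurable; they are a bookkeeping
convention, not physics, so any placement that brackets the filter gives
the same net count on trajectories whose ions fully traverse the pore.

Conductance uses the net signed count (inward minus reverse), because
conductance measures net charge transport:

$$ g = \frac{N q e}{t\, E L_z}\cdot\frac{1}{f_{\mathrm{ECC}}} . $$

The nominal integer charge q enters, not the ECC-scaled one: charge
scaling models electronic screening and does not change the charge an ion
physically carries across the membrane; correspondingly the effective
field acting on scaled charges is E*f_ECC, which is where the 1/f_ECC
factor comes from. Replicate SDs use the sample formula; fold-change
errors propagate to first order (delta method); I-V slopes are
least-squares fits through the origin, `sum(VI)/sum(V^2)`. The Arrhenius
helper `exp(ddG/RT)` converts a barrier difference into a rate ratio --
with R = 0.0083144621 kJ/mol/K throughout. A 19 kJ/mol difference at
310 K gives a ratio of about 1,590 (~1,600:1); the same arithmetic at
the same temperature yields about 2,000:1 only for ddG near 19.6 kJ/mol,
so quoted selectivities of both magnitudes correspond to barrier
differences well within typical PMF error bars.

# Selectivity-filter occupancy and kinetics

Frames are labelled by the number of ions inside the filter extent: one
ion is state 1; two ions both within the upper sites (S1U, S2U) are 2U,
both within the lower sites (S1L, S2L) are 2L; anything else (empty,
mixed, or more than two ions) is "other". The default site intervals --
filter extent [-5, 5] A, S2L [-4, -1.5], S2U [-1.5, 0.5], S1L
[0.5, 2.5], S1U [2.5, 5], vestibule above -- bracket the printed
single/double-ion density peaks (around -2.8 and +1.7 A) while keeping
the upper/lower pairs disjoint; the exact boundaries are deliberately
user-tunable because they are a convention, not a measurement.

Transition rates are per-time estimates, transitions divided by time
spent in the origin state (final frame excluded from the denominator),
with Poisson standard errors. Frame resampling introduces a bias of
order k*dt (transitions hidden within one frame), so the frame spacing
should resolve the fastest rate: at dt = 1 ps and rates up to 20 ns^-1,
k*dt = 0.02 and the bias is far below the statistical error of runs with
~10^5 frames. The default saving stride of the kinetic Monte Carlo
generator is 10 ps, mimicking typical MD frame saving; analyses that
estimate rates near or above 100 ns^-1 should lower it.

Coordination numbers use a single distance cutoff, default 3 A, with the
boundary included (closed comparison) -- the convention is stated because
"a cutoff of 3 A" alone does not fix it. Water oxygens use the same
cutoff as carboxylate oxygens unless configured otherwise. The z-density
profile is the average ion count per bin (default width 0.2 A, sub-A as
density plots require), so it sums exactly to the time-averaged ion count
in the profiled region -- a conservation law the tests assert.

# Synthetic generators: what they emulate, and what they do not

* `toyLandscape()` provides closed-form surfaces (bowl, double well with
  analytic saddle, ridge-with-corridor, 1D triple well, and a 3-CV
  surrogate whose three basins advance in z-order like a knock-on ion
  file) with their analytic facts attached.
* `wtMetadynamics1d()` is an overdamped-Langevin walker with
  well-tempered hill deposition: hills of height
  `omega*exp(-V/( (gamma-1) RT))` every 1 ps, defaults omega = 5 kJ/mol,
  sigma = 0.02 nm, gamma = 5 -- standard hill parameters for nm-scale
  CVs. The free energy estimate is the well-tempered identity
  `F = -gamma/(gamma-1) * V`, and the reported surface is the time
  average of the min-shifted estimate over the second half of the run,
  the usual way a converged PMF is quoted; averaging suppresses the
  hill-scale corrugation of any single snapshot. Hills are mirrored
  across the reflecting domain walls so the bias stays consistent with
  the reflected walker density at the edges. The default run length
  (10 ns of walker time, ~10^4 hills) leaves final hill heights near
  0.01 kJ/mol, i.e. converged for barriers around 10 kJ/mol; the
  acceptance script uses 20 ns for extra seed-to-seed margin.
* `simulateKnockonKmc()` is an exact Gillespie simulation of the
  three-state cycle 1 -> 2U -> 2L -> 1 (reverse rates optional), with a
  permeation event on each completed 2L -> 1 transition, resampled onto a
  uniform frame grid. For the irreversible cycle with rates
  (10, 20, 5) ns^-1, the stationary occupancies are proportional to the
  mean dwell times (1/10, 1/20, 1/5), i.e. (0.286, 0.143, 0.571), and
  the event rate is the harmonic cycle rate 1/(0.1+0.05+0.2) =
  2.86 ns^-1 -- the analytic values the estimators are tested against.
* `simulateMultiIonLangevin()` integrates
  `dz_i = (-U'(z_i) + qE + sum_j f_rep)/gamma dt + sqrt(2RT dt/gamma) dW`
  by Euler-Maruyama with periodic re-entry. The pair force is a
  screened-Coulomb surrogate `A*sign(d)*exp(-|d|/lambda)/d^2` (defaults
  A = 500 kJ/mol*A, lambda = 3 A) strong enough that two ions essentially
  never swap order in single file -- an explicit stand-in for full
  electrostatics, not a model of them. A positive field drives cations
  toward -z, the physiological inward direction, so inward events are
  downward crossings. The configuration constructor rejects time steps
  whose free-flight displacement SD reaches 0.5 A, and the integrator
  aborts if any step exceeds a quarter box.
* `synthetic_coordination` frames add i.i.d. Gaussian noise to a
  geometric layout and emit their own ground-truth counts, so the
  analysis path can be checked against the generator exactly.

What passing tests on these generators shows: the estimators are
unbiased and consistent on data whose ground truth is known, under the
event-rate, noise and sampling regimes stated above. What it does not
show: anything about force-field accuracy, sampling convergence of real
MD, non-Markovian filter dynamics, or coupling between ions beyond
screened repulsion. Real trajectories also wrap several ions and species
at once; the analysis functions take per-ion columns and species labels
for that reason.

# ECC topology editing

The patcher operates on a restricted topology grammar (bracketed section
headers, whitespace-separated records, ";" comments) sufficient for the
three edits it performs: multiplying the charges of ions and of
charged-residue terminal atom groups by f_ECC (default 0.87, the value
that reproduces divalent conductance in the CaV setting; 1/f restores
the file), replacing the calcium Lennard-Jones sigma (default
0.24357170954 -> 0.27 nm, refitting the ion-water oxygen distance), and
deleting pair-override (NBFIX) records for ion-oxygen pairs, which would
otherwise double-correct what the charge scaling already corrects. The
terminal-atom table ships as an editable convention (carboxylate group
for Asp/Glu, ammonium for Lys, guanidinium for Arg, imidazolium for
protonated His) because force fields partition residue charge slightly
differently; each group sums to the residue's formal +-1 charge so the
scaled group sums to +-f_ECC. Every unedited line survives
byte-for-byte; edited lines keep their column alignment when the new
number fits the old slot, and an audit table records every change so a
no-op selection fails loudly instead of silently not scaling.

# Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data
at deliberately modest sizes: 30x30 and 12^3 grids for path searches
(where exhaustive oracles are still affordable), 10^5-frame kMC runs,
200-replicate conductance ensembles, and 10-20 ns toy metadynamics runs
-- sizes at which every stochastic check has comfortable statistical
margin while the whole suite stays fast. Every generator takes a
mandatory seed and uses no hidden global RNG state; identical
(seed, config) pairs reproduce outputs bit for bit, and the pipeline
writes its resolved configuration next to its outputs so deterministic
stages can be replayed.

# Known limitations

* The CG path search is exact on smooth, deep-well surfaces (and always
  between adjacent basins) but can overestimate the cost on rough
  surfaces; use `verify = TRUE` to quantify, or call
  `shortestResistancePath()` directly when grids are small enough.
* Rate estimation from resampled frames carries an O(k dt) bias; choose
  the frame spacing to resolve the fastest rate of interest.
* The Langevin surrogate is one-dimensional and overdamped; it emulates
  single-file kinetics and event statistics, not hydration, side-chain
  flexibility, or 3D electrostatics.
* The topology grammar covers atoms/atomtypes/pair-override records
  only; preprocessor directives and merged molecule blocks are out of
  scope.
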