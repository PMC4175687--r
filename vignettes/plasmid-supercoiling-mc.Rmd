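---
title: "Simulating plasmid DNA supercoiling with a local three-vertex Monte Carlo move"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating plasmid DNA supercoiling with a local three-vertex Monte Carlo move}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidmc)
```

## The model

Closed circular (plasmid) DNA in its native state is supercoiled: the
deficit in the linking number of its two strands relative to the relaxed
molecule is absorbed partly as twist and partly as writhe, the coiling of
the helix axis in space. `plasmidmc` simulates this at the classical
coarse-grained level: the molecule is reduced to its axis, a closed
polyline ("skeleton") of `s` equal segments of length `l`, with each
segment standing in for roughly 30 base pairs.

**Skeleton construction.** Given a plasmid of `n` base pairs and bounds
`min < 30 < max` on the admissible base pairs per segment, the segment
count is `s = round(n / i)` for the `i` minimizing `|n - round(n/i) * i|`
(ties resolved toward `i` nearest 30, then the smaller `i`). The initial
conformation is the planar regular `s`-gon with circumradius
`R = l / (2 sin(pi/s))`, which makes every chord exactly `l`; we set
`l = i * rise` (rise 3.3 Å/bp) so the perimeter tracks the contour length
as closely as the integer rule allows. For pUC19 (2686 bp) this yields
`s = 79` segments of 34 bp, `l = 112.2` Å.

**Elastic energy.** A conformation's energy is `E = E_b + E_t` with

* bending: `E_b = (k_B T alpha / 2) * sum_i Theta_i^2`, where `Theta_i` is
  the angle between consecutive segment directions and `alpha = 2.403` is
  the dimensionless bending constant;
* torsion: `E_t = 2 pi^2 C (dLk - Wr)^2 / L`, quadratic in the part of the
  linking-number deficit not absorbed by writhe. `C = 3e-28` J·m is the
  torsional rigidity, `L` the contour length in meters, `dLk = sigma *
  n / 10.5` the deficit set by the superhelix density `sigma` (default
  -0.04, the value of the reference experiments; physiological estimates
  lie in [-0.07, -0.05]) with a helical repeat of 10.5 bp/turn.

With these defaults the relaxed pUC19 circle starts at about `7e-19` J
(dominated by torsion, since `Wr = 0`), roughly 170 `k_B T` at 293 K, and
the energy scale per unit writhe change near equilibrium is a few `k_B T`
-- which is what makes Metropolis sampling effective here.

**Writhe.** The production path follows the auxiliary-chain method: the
auxiliary chain is the skeleton displaced infinitesimally along the `z`
axis, so the linking number of the pair equals the *directional writhe*
(the sum of signed crossings of the `z = 0` projection over non-adjacent
segment pairs -- an integer), the twist of that vertical ribbon is
accumulated per vertex by parallel transport of the projected `z`
direction, and `Wr = Lk - Tw`. This identity is exact for polygons, and
the package verifies it against an independent Gauss double-integral
oracle (`writhe_gauss()`, closed-form solid angles per segment pair) to
`1e-13` in the tests. Adjacent segments are excluded from crossing tests:
two straight segments sharing a vertex cannot cross elsewhere in
projection. Degenerate projections (crossings at segment ends, collinear
overlaps, segments parallel to `z`) are handled by re-scanning after a
small random rigid rotation; the writhe is projection-invariant, so this
changes nothing but the diagram.

**Knot rejection.** Deformation moves can in principle pass one strand
through another, changing the topology; a plasmid must stay unknotted. On
every trial (before any energy evaluation, so rejected trials cost no
energy computation) the projected crossing diagram is converted to an
Alexander matrix via the Wirtinger presentation -- underpasses numbered
along the chain, one generator per arc, rows `(t, -1, 1-t)` or
`(1, -t, t-1)` at positive/negative crossings with the over-arc column --
and `|Delta(-1)|` is compared with the unknot value 1. The verdict is
computed in exact modular integer arithmetic (Gaussian elimination modulo
two 31-bit primes), so it is immune to floating-point determinant growth
on dense diagrams; floating-point values at `t = -1` and `t = -2` are also
reported for inspection. The trefoil and figure-eight fixtures evaluate to
3 and 5.

## The moves

**Local three-vertex move.** A mobile vertex `v_m` is chosen uniformly.
Its new position is sampled in spherical displacement coordinates relative
to the fixed vertex `v_{m-2}` -- radial displacement uniform on `[-r, r]`
with `r = 2 * 3.3` Å (twice the base-pair rise), angular displacements
uniform -- and accepted only inside the intersection of the neighborhood
sphere `N_m` (radius `r` about the old position) with the reach spheres of
radius `2l` about `v_{m-2}` and `v_{m+2}`. Sampling note: angular
displacements nominally range over `[-pi, pi]`, but a uniform sample from
that box lands in `N_m` with probability around `1e-4`; we therefore
restrict the angular box to the sub-box that can reach `N_m` before
rejection sampling. A uniform distribution on a box, conditioned on a
subset, is identical to the uniform distribution on any smaller box
containing that subset, so this changes nothing statistically while
raising the first-attempt success rate to the tens of percent (the run
object reports the measured rate; it is highest in bent conformations and
a few percent on the flat initial circle, where the admissible region is a
thin lens). After `v_m` moves, each semi-mobile flank `v_{m±1}` must stay
at distance `l` from both of its neighbors, i.e. on the circle in which
the two spheres of radius `l` around `v_{m±2}` and the new `v_m`
intersect. We construct that circle exactly (center at the chord midpoint,
radius `sqrt(l^2 - D^2/4)`), place the flank at the projection of its old
position onto the circle, and rotate it by an independent random
crankshaft angle `psi ~ U[-pi, pi)` about the `v_{m±2}`-`v_m` axis. The
constrained-projection step absorbs the piston-crank angular correction
that relates a radial displacement of `v_m` to the flank's rotation on its
sphere; building the circle exactly guards the length invariants by
construction, and the tests confirm closure and equal lengths to `1e-14`
relative over `1e4` trials, with exactly three vertices displaced.
`reverse_local_move()` reconstructs the parameters that map the trial back
onto the original conformation and round-trips to `1e-9`.

**Baselines.** The standard crankshaft picks two distinct non-adjacent
vertices and rigidly rotates the shorter arc between them by `theta ~
U[-pi, pi)` about their connecting axis (ties rotate the arc following the
first vertex). The biased crankshaft draws `theta` from an adaptive range
`[-theta_max, theta_max]`: after every 1,000-step slice, `theta_max` is
multiplied by `1.05` if more than half the slice's trials were accepted
and by `0.95` if fewer, clipped to `(1e-4, pi]` -- a multiplicative
controller targeting 50% acceptance. Initial ranges are 2.043 rad
(constant-temperature runs) and 1.854 rad (annealing runs). Reptation
removes the segment vector following `v_j` from the cyclic sequence of
segment vectors and reinserts it after `v_i`; this is the one reading of
"translate the sub-chain one segment along the contour" that preserves all
segment lengths exactly (it is a permutation of segment vectors), and it
rigidly translates the sub-chain by the moved vector while shifting its
labels by one.

## The Monte Carlo driver

Each step proposes a trial, runs the knot gate, and then accepts with the
Metropolis rule: always if the energy decreased, otherwise with
probability `exp(-dE / (k_B T_M))` (the `T_M = 0` limit rejects all uphill
moves). Because the knot gate already performs the full projected-crossing
scan on every trial, the directional writhe comes for free from the same
scan and the engine recomputes bending and twist sums outright (both are
linear in `s`); the exported `incremental_energy_update()` implements the
genuinely incremental algebra -- only affected joints and crossing pairs
-- and is held to `1e-9` agreement with full recomputation in the tests,
with a 1000-move drift bound of `1e-6`. Setting `knot_interval > 1` skips
only the Alexander determinant on intervening steps.

In annealing mode the temperature starts at 350 K and, at the end of each
1,000-step slice, is multiplied by 0.9 whenever the slice's mean energy
exceeded 0.9 times the previous slice's mean, clamped at a 10 K floor. As
printed, the rule cools whenever the energy has *not* dropped by 10% in a
slice -- counterintuitive but implemented verbatim; in practice it cools
nearly every slice once the fast initial relaxation is over, reaching the
floor near step 35,000 under the default conditions. "Steps to
equilibrium" are reported by `equilibrium_step()`: the first step whose
trailing 10,000-step mean energy is within 10% of the mean over the final
50,000 steps.

## Synthetic data and fixtures

`make_fixture()` builds the closed test polygons: circles, trefoil and
figure-eight knots (equal-arc resampling of the standard parametric
curves, then iterative relaxation of `sum (L_i - l)^2` until all segment
lengths agree to `1e-12` relative), and perturbed circles (seeded Gaussian
vertex noise, re-equalized). These exercise exactly the geometry the
simulator produces -- closed, equal-segment, moderately bent polylines --
but none of the sequence-level realism of actual plasmids: there is no
excluded volume, no electrostatics, no sequence-dependent stiffness, and
the energy model is the two-term elastic form above. Passing tests
therefore certify the geometry, topology and sampling machinery, not
agreement with experimental biophysics of any particular plasmid.

## Reproduced behavior and known discrepancies

At the reduced scale used throughout (100,000 constant-temperature steps,
200,000 annealing steps, three seeds -- chosen so the whole suite runs in
minutes on one core), the package reproduces the reference behavior in
most respects: constant-temperature acceptance near 45% for the local move
versus under 30% (standard crankshaft, every 10,000-step slice) and above
30% (biased); a common annealing energy plateau close to `0.14e-19` J
across all three move types; much smaller per-trial displacements for the
local move with accumulated displacement growing from the first slices and
flattening over time; and the biased-crankshaft angle range decreasing
over the run.

Three reference observations do not reproduce under the stated geometry,
and are left as measured rather than tuned toward:

* *Zero knots for the local move.* With flank rotations drawn from the
  full `[-pi, pi)` range, a flank can sweep an arc of up to twice the
  flank-circle radius (tens of Å in bent conformations) and occasionally
  threads a strand through a nearby loop: a handful of genuinely knotted
  trials (Alexander value 3, stable under rigid rotations of the
  conformation) appear per 100,000 steps and are duly rejected by the
  gate. Bounding the flank arc by `r` eliminates knots entirely but
  raises constant-temperature acceptance to ~90%, far from the reported
  45%; no flank-angle range is stated that reconciles both observations,
  so the full range is kept and the gate does its job.
* *Early annealing acceptance.* The local move's first-10,000-step
  acceptance under annealing measures ~50% here against a reported >60%
  (the baselines' ordering -- local far above biased above standard -- is
  reproduced).
* *Equilibration step.* The annealing energy keeps creeping downward
  slowly after the temperature floor is reached; the trailing-mean rule
  detects the plateau near step 150,000 for the local move here, versus
  approximately 80,000 (read off a figure) in the reference, and the
  crankshaft baselines -- which take much larger steps -- get near their
  (slightly higher) plateaus sooner rather than later.

## Numerical choices

Closure and equal segment lengths are asserted at `1e-9` relative
throughout (construction is exact to rounding, ~`1e-14`). Crossing
parameters within `1e-9` of a segment end, collinear overlapping
projections, near-coincident strand heights at a crossing, and segments
parallel to `z` all trigger projection resampling (up to 5 random
rotations of ~`1e-3` rad). Bend angles use `atan2(|u × w|, u·w)` for
stability near 0 and pi. The local move's rejection sampling is capped at
100 attempts per mobile vertex, after which a new vertex is drawn (the
engine allows 50 redraws per step). Units: coordinates in Å; the single
conversion `1e-10` m/Å enters the torsional term through `L`, making `E`
joules consistent with `k_B` in J/K. All randomness flows through R's RNG
(`set.seed` reproduces runs bit-identically, including inside the C++
engine).
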