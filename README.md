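# plasmidmc

Metropolis Monte Carlo simulation of plasmid (closed circular) DNA
supercoiling, built around a local three-vertex deformation move that
preserves the size and connectivity of every segment of the DNA skeleton,
with the standard crankshaft, biased (adaptive-angle) crankshaft and
reptation moves as baselines.

## The model

The molecule is reduced to its axis: a closed polyline of `s` equal
segments of length `l`, about 30 bp per segment (`s = round(n/i)` for the
`i` in `[min, max]` minimizing `|n - round(n/i)·i|`; pUC19's 2686 bp give
`s = 79` segments of 34 bp). The elastic energy of a conformation is

    E = E_b + E_t
    E_b = (k_B T α / 2) Σ_i Θ_i²                (bending, α = 2.403)
    E_t = 2π² C (ΔLk − Wr)² / L                 (torsion, C = 3·10⁻²⁸ J·m)
    ΔLk = σ · n / 10.5                          (linking-number deficit)

where `Θ_i` is the angle between consecutive segments, `L` the contour
length, `σ` the superhelix density (−0.04 by default) and `Wr` the writhe
of the axis. Writhe is computed by the auxiliary-chain method — the
linking number of the skeleton with its vertical offset copy (an integer
equal to the sum of signed crossings of the z-projection) minus the twist
of that ribbon, `Wr = Lk − Tw` — and cross-checked against an exact
Gauss double-integral oracle. Each Monte Carlo trial is screened by an
Alexander-polynomial knot gate (`|Δ(−1)| = 1` for the unknot, evaluated in
exact modular arithmetic) *before* any energy is computed, and then
accepted by the Metropolis rule at the experiment temperature, either
constant (293 K) or annealed from 350 K to 10 K by a 0.9 cooling factor
applied per 1,000-step slice whenever the mean energy failed to drop 10%.

In the local move, a randomly chosen mobile vertex `v_m` is resampled
inside the intersection of a small sphere of radius `r = 2Δ` (Δ = 3.3 Å,
the rise per base pair) about its old position with the two spheres of
radius `2l` about the fixed vertices `v_{m±2}`; the flanking vertices
`v_{m±1}` are then placed on the exact two-sphere intersection circles and
rotated by random crankshaft angles. Only three vertices move per trial.

## Worked example

```r
library(plasmidmc)

sk <- skeleton_from_bp(2686)          # pUC19
sk
#> dna_skeleton: 79 vertices, segment length 112.2000 A, perimeter 8863.8 A

total_energy(sk, physical_constants(), n_bp = 2686)$E
#> [1] 7.019225e-19                     # relaxed circle, Wr = 0: all torsion

sim <- run_simulation(2686, "local", steps = 20000, temperature = 293, seed = 1)
sim
#> mc_simulation: local move, 20000 steps
#>   acceptance 50.6%, knot rejections 0, final E 7.547e-19 J, final Wr -1.191

slice_report(sim, 10000L)[, c("slice_start", "accepted", "ratio", "mean_E")]
#>   slice_start accepted  ratio       mean_E
#> 1           1     5690 0.5690 7.764437e-19
#> 2       10001     4432 0.4432 7.570561e-19
```

About half the local-move trials are accepted at 293 K, and the writhe
drifts negative as the molecule converts its linking-number deficit into
supercoiling. An annealing run (`anneal = c(350, 10)`) drives the energy
down to a plateau near `0.14e-19` J as `Wr` approaches `ΔLk ≈ −10.2`.

The same functionality is scriptable:

```sh
exec/plasmidmc init --bp 2686 --out skeleton.xyz
exec/plasmidmc run --bp 2686 --move local --steps 10000 --temp 293 \
    --seed 1 --out metrics.csv --slices slices.csv
exec/plasmidmc run --bp 2686 --move local --steps 200000 --anneal 350:10 \
    --seed 1 --out anneal.csv --traj traj.xyz
exec/plasmidmc fixtures --kind trefoil --s 30 --out trefoil.xyz
```

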