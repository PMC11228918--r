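# prenuc

Analysis of **prenucleation molecular clustering** of a drug-like solute in
organic solvents, for crystallization and nucleation researchers. Long before
a crystal nucleus appears, under-, at- and supersaturated solutions of small
organic molecules contain solute-rich mesoscale clusters (hundreds of nm).
`prenuc` provides the full analysis chain for such studies — the packaged
system is salicylamide in methanol, acetonitrile and ethyl acetate:

* **DLS sizing** — second-order cumulant analysis of intensity
  correlograms, ln(g₂−1) = ln β − 2Γτ + μ₂τ², and conversion to the
  solvodynamic diameter via the Stokes–Einstein relation
  D_h = k_B T / (3π η D_t) with D_t = Γ/q².
* **Cluster occupancy and growth kinetics** — number of solute molecules
  per cluster N = (π/6) D³/ϑ, forward-difference growth rates, and a
  diagnostic of the rate-limiting mechanism: Ṅ/r constant in time implies
  diffusion-limited attachment, Ṅ/r² constant implies interface-transfer
  control.
* **Classical nucleation theory** — driving force RT ln S and critical
  nucleus diameter D_c = 4γϑ_m/(RT ln S), plus descriptive linear
  correlations between cluster size, nucleation driving force, interfacial
  energy, solvation free energy and IR carbonyl shift.
* **Trajectory analyses** — standalone operators on periodic-box
  trajectories (extended XYZ + topology CSV): single-linkage distance-cutoff
  clustering, center-of-mass radial distribution functions, geometric
  hydrogen-bond detection with continuous/intermittent lifetime curves,
  angle–distance π-stacking free-energy landscapes, and Coulomb +
  Lennard-Jones pair interaction energies.
* **Synthetic-data generators** — every input above can be generated with
  embedded ground truth (growth laws integrated exactly, planted cluster
  partitions, telegraph hydrogen-bond dynamics, planted stacking mixtures),
  making the whole pipeline testable end to end.

## Worked example

Reproduce the study's clustering-and-nucleation tables — measured cluster
sizes are echoed as provenance-labelled data, critical nucleus diameters are
recomputed from the printed interfacial energies:

```r
library(prenuc)
tb <- reproduce_tables()
tb$table_target
#>                     solvent    S D_s_72h_nm provenance_D_s D_c_nm provenance_D_c
#> ethyl acetate ethyl acetate 1.05       2046       measured  8.994       computed
#> acetonitrile   acetonitrile 1.05       1499       measured 11.251       computed
#> methanol           methanol 1.05       1149       measured 13.374       computed
```

At equal weak supersaturation (S = 1.05) the measured clusters are about
two orders of magnitude larger than the critical nucleus, and the solvent
producing the largest clusters (ethyl acetate) is the one where nucleation
is easiest (lowest driving force) — the correlation that motivates the
analysis.

Simulate a growth run under interface-transfer control at the study noise
level and recover the mechanism:

```r
s <- gen_growth_series("interface_transfer", sigma = 0.02, seed = 42)
r <- regime_statistics(s, molecular_constants(0.169))
#> trend_diff = 1.642  trend_int = 0.209  classification = interface_transfer
```

The rate-per-surface-area series is flat (|trend| = 0.21, below the 0.6
threshold) while the rate-per-radius series trends strongly upward, so the
series is classified as interface-transfer limited — growth limited by
molecular attachment at the cluster surface, not by diffusion through the
solution.

Size a noisy synthetic correlogram of a 400 nm cluster:

```r
cg <- gen_correlogram(400, pdi = 0.1, sigma = 1e-3, seed = 42)
size_correlogram(cg)
#>   gamma_per_us    pdi   beta diameter_nm
#> 1    0.0007591 0.1018 0.8001       399.6
```

A thin command-line front end over the same functions lives at
`inst/cli/prenuc.R` (`tables`, `run --config study.yaml`, `simulate ...`).

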