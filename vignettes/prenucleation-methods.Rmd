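---
title: "Models and methods behind prenuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prenuc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prenuc)
```

`prenuc` analyses prenucleation molecular clustering of a drug-like solute
(the packaged study system is salicylamide in methanol, acetonitrile and
ethyl acetate). This vignette explains the models, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data
generators do and do not emulate. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. Sizing clusters from photon-correlation data

Dynamic light scattering measures the normalized intensity autocorrelation
$g_2(\tau) - 1$. For a quasi-monodisperse population the decay is
$\beta e^{-2\Gamma\tau}$ and the second-order cumulant expansion

$$\ln(g_2 - 1) = \ln\beta - 2\Gamma\tau + \mu_2\tau^2$$

yields the mean decay rate $\Gamma$, the coherence factor $\beta$ and the
polydispersity index $\mathrm{PDI} = \mu_2/\Gamma^2$. `fit_cumulants()`
performs this fit by weighted least squares with weights $(g_2-1)^2$, the
standard stabilization of the log-linearization (equal weights in log space
over-weight the noisy tail). The default fit window keeps lags where
$g_2 - 1 \ge 0.1\,\beta_0$, with $\beta_0$ estimated from the head of the
decay; this is common instrument practice and avoids the noise floor. A
fitted $\mu_2 < 0$ (possible under noise) is truncated to zero so the PDI
is always non-negative.

The decay rate converts to a solvodynamic (hydrodynamic) diameter through
the scattering vector $q = 4\pi n \sin(\theta/2)/\lambda$ and the
Stokes–Einstein relation:

$$D_t = \Gamma/q^2, \qquad
  D_h = \frac{k_B T}{3\pi \eta D_t}.$$

Defaults describe a typical backscatter instrument
($\lambda = 633$ nm, $\theta = 173^\circ$); refractive index, temperature
and viscosity are per-solvent inputs. A point worth noting because it is
easy to get backwards: with $\Gamma$ (hence $D_t$) fixed by the
measurement, a *higher* viscosity implies a *smaller* inferred diameter.

Design choice: a second-order cumulant fit, not a regularized inverse
Laplace transform (CONTIN). The cumulant route is the instrument-standard
Z-average method, is well-conditioned on single-population decays — the
regime relevant here — and has exactly three interpretable parameters. It
cannot resolve multimodal size distributions; on a bimodal decay it
returns an intermediate rate (a property the tests assert), which is the
correct reading of its output, not a defect of the fit.

## 2. Cluster occupancy and growth kinetics

The number of solute molecules per cluster (NSMC) models the cluster as a
solute-dense sphere of the solvodynamic diameter $D$:

$$N = \frac{\pi D^3}{6\,\vartheta},$$

with $\vartheta = 0.169\ \mathrm{nm}^3$ the salicylamide molecular volume
from its crystal structure. Taken literally at the measured cluster scale
($D \approx 400$ nm) this gives $N \approx 2\times 10^8$, while dilute
prenucleation clusters are usually discussed as holding $10^3$–$10^4$
molecules; the formula assumes solute-dense packing, which real (heavily
solvated) clusters do not satisfy. `prenuc` applies the formula as defined
and leaves the interpretation of its magnitude to the user; no corrective
packing fraction is guessed.

The growth rate is the simple forward difference
$\Delta N / \Delta t$ between consecutive measurements, reported at
interval midpoints, with the radius linearly interpolated to the same
midpoints for consistency.

### Growth-regime diagnostic

Two transport-limited growth laws are distinguished:

* **diffusion control** — attachment flux scales as $D C / r$ times the
  surface area, so $\dot N \propto r$ and $\dot N / r$ is constant in time;
* **interface-transfer control** — the flux per unit area is independent of
  $r$, so $\dot N \propto r^2$ and $\dot N / r^2$ is constant.

`regime_statistics()` forms both ratio series and summarizes each by a
dimensionless normalized trend: the OLS slope multiplied by the time span
and divided by the series mean. The mechanism whose ratio is flatter wins;
the result is `indeterminate` when both trends exceed a threshold in
magnitude or when their magnitudes differ by less than a margin.

**Threshold calibration.** The default threshold is 0.6 and the margin 0.1,
both user-settable. The calibration logic: with diameters carrying 2 %
multiplicative noise (typical of repeated DLS size determinations) on the
3 h / 72 h measurement grid, the *matching* ratio's normalized trend is
zero-mean noise whose 95th percentile is about 0.47 — cubing $D$ into $N$
and differencing amplifies measurement noise substantially. The *wrong*
ratio inherits the full dynamic range of the radius: over a typical run the
radius grows roughly eightfold, which puts a floor of about 0.8 on the
wrong mechanism's |trend|. The value 0.6 sits between the noise tail and
that floor. (A tighter threshold such as 0.25 looks natural but rejects a
third of genuinely diffusion-limited series as indeterminate at this noise
level.) The recovery rate at these settings — at least 95 % correct over
200 synthetic series per mechanism — is asserted by the test suite.

### Supersaturation normalization and interpolation

Concentrations are normalized by solubility, $S = x/x^*$; cluster sizes
measured at several $S$ are compared across solvents at a common target
(default $S = 1.05$) by piecewise-linear interpolation of $D_s$ against
$S$. Interpolation is linear in $S$ (not $\ln S$, not $\log D_s$), exact on
affine data and order-insensitive; extrapolation beyond the supplied
bracket is performed linearly but flagged and warned. Note that the
packaged study's printed interpolated sizes at $S = 1.05$ are *not*
reproducible from the two printed bracketing points by linear interpolation
in any of those variables — the original point set behind them is
under-determined — so the package carries the printed values as measured
data with a provenance label and never overwrites them.

## 3. Classical nucleation theory comparison

The thermodynamic driving force per mole is $RT\ln S$ and the critical
nucleus diameter (Gibbs–Thomson) is

$$D_c = \frac{4\gamma\vartheta_m}{RT\ln S},$$

with $\gamma$ the crystal–solution interfacial energy (mJ/m²; fitted to
nucleation-induction data in earlier work and consumed here as input) and
$\vartheta_m = 1.01853\times10^{-4}$ m³/mol the molar volume. The printed
source labels this quantity a "molecular volume", but its units and its
role in reproducing the tables identify it as a molar volume; `prenuc`
names it accordingly. No activity-coefficient correction is applied,
matching how the packaged tables were produced. Unit conversions
(mJ/m² → J/m², m → nm) are centralized and covered by exactness tests,
because the formula mixes unit systems and silent unit bugs are the main
risk.

**Temperature.** The packaged tables are reported at a nominal 298 K, but
reproducing every printed $D_c$ cell to the printed 0.01 nm requires
$T = 298.15$ K (25 °C) — with 298 K four of nine cells drift by
0.01–0.02 nm. The package therefore uses 298.15 K as the study temperature
(`salicylamide_constants()`), treating the printed 298 K as a rounded
nominal value.

Correlations among cluster size, driving force, interfacial energy,
solvation free energy and the IR carbonyl shift are reported descriptively
(slope, intercept, Pearson r) with no p-values: three solvents cannot
support inference.

## 4. Trajectory analyses

All trajectory operators work on a plain frame structure (time, orthorhombic
box, coordinate matrix in nm) plus a per-atom topology table; the extended
XYZ reader/writer and the topology CSV format are the package's exchange
formats. Triclinic boxes are rejected outright — the contract is kept
narrow and testable. All distances use the minimum-image convention, which
the tests pin against a 27-image enumeration oracle.

* **Clustering** (`cluster_frame()`): single-linkage components of the
  contact graph; two solute molecules are linked when their minimum
  heavy-atom pair distance is at most the cutoff (default 0.35 nm,
  inclusive). The stated cutoff criterion does not name atoms; the
  heavy-atom minimum is the common convention, and `"any"`-atom and
  center-of-mass linkage are available as options. Labels are
  deterministic (smallest member molecule id). `cluster_count_series()`
  adds the per-frame counts and a quadratic-in-time fit, the conventional
  smooth summary of early coalescence.
* **Radial distribution function** (`rdf()`): mass-weighted molecular
  centers (unwrapped across the boundary before averaging), default range
  3 nm, bin width 0.02 nm, reference density $N_b/\langle V\rangle$. A
  range beyond half the smallest box edge is an error, never a silent
  truncation.
* **Hydrogen bonds** (`hbond_events()`): donor–acceptor distance
  $\le 0.35$ nm and hydrogen–donor–acceptor angle (vertex at the donor,
  between the donor→H and donor→acceptor vectors) $\le 30^\circ$, both
  inclusive with a $10^{-12}$ float guard so the stated criteria are
  reproducible exactly. `hbond_lifetime()` offers both common $P(t)$
  definitions — *continuous* survival (bond intact at every intermediate
  frame) and *intermittent* autocorrelation (breaking and reforming
  allowed) — because published lifetime curves often leave the definition
  implicit. Continuous $P(t)$ never exceeds intermittent $P(t)$ and both
  start at 1; the default is continuous. Lag times use the mean frame
  spacing taken from the file.
* **Stacking landscape** (`stacking_landscape()`): for every solute pair,
  the ring-centroid distance and the angle between least-squares ring-plane
  normals, histogrammed on a 5° × 0.01 nm grid (distances capped at
  1.5 nm) and converted to $F = -k_BT\ln(P/P_{max})$; the minimum is
  exactly 0 at the modal bin and empty bins are $+\infty$ (masked), never
  clipped. Because a plane has no canonical normal direction, the angle is
  spread over [0°, 180°] with parallel stacking appearing near both ends,
  and only the θ ↔ 180° − θ folded map is strictly invariant under rigid
  rotations; degenerate (collinear) rings are skipped and counted.
* **Pair energies** (`pair_interaction_energy()`): Coulomb
  $f q_i q_j / r$ ($f = 138.935458$ kJ·nm·mol⁻¹·e⁻²) plus Lennard-Jones
  with Lorentz–Berthelot combination, plain inclusive cutoff (default
  1.2 nm), no Ewald summation — documented as such — normalized per
  molecule of the first group.

## 5. Synthetic data: what it emulates, what it does not

Every generator is deterministic under a fixed seed and embeds its ground
truth in the returned object; downstream recovery tests read the truth only
from there.

* `gen_growth_series()` integrates the two growth laws exactly
  (lsoda, rtol $10^{-8}$; both laws also have closed forms used as the
  integrator's independent oracle) and adds multiplicative Gaussian noise
  to the sampled diameters. Defaults are the study conditions: start at
  50 nm, sample every 3 h to 72 h, noise 2 % of $D$, and rate constants
  ($a = 2\times10^4$ molecules·h⁻¹·nm⁻¹, $b = 180$
  molecules·h⁻¹·nm⁻²) chosen once from the closed forms so growth spans
  50 → ≈ 400 nm over 72 h, the saturated-solution scale.
* `gen_correlogram()` produces truncated second-cumulant decays with
  additive noise on a geometric lag grid.
* `gen_planted_config()` builds periodic-box configurations whose
  single-linkage partition at the stated cutoff *equals* the planted
  partition by construction: chains with intra-chain spacing below the
  cutoff, chain centers rejection-sampled with clearance above it, and an
  optional scripted merge schedule for multi-frame coalescence. The
  bundled 12-atom rigid molecule (aromatic ring, amide donor/acceptor,
  phenolic donor) exercises ring-plane fitting and hydrogen-bond roles; its
  charges and LJ parameters are synthetic and carry no force-field claim.
* `gen_bond_telegraph()` simulates independent two-state Markov bonds, so
  the ensemble continuous survival is analytically $e^{-k t}$.
* `gen_stacked_pair_frames()` plants a parallel/T-shaped ring-pair mixture
  with jitter small enough that each population stays in one basin.

What passing these tests shows: the estimators invert their own forward
models at realistic noise, and the geometric operators agree with
brute-force oracles. What it does not show: anything about real solvated
clusters — the generators have no solvent structure, no force-field
fidelity, no aggregation–fragmentation physics, and no model of why
measured growth plateaus. Experimentally printed quantities (cluster
sizes, solvation free energies, IR peaks) therefore flow through the
pipeline as provenance-labelled data, never as recomputed results.

## 6. Problem sizes and degenerate inputs

The bundled studies run at desk scale by design: recovery suites use
100–200 replicates, the uniform-RDF reference uses 1000 point molecules
over 100 frames, the lifetime oracle 500 bonds over 100 frames, and the
stacking mixture 1000 frames — sizes at which the binomial/Monte-Carlo
error of each check sits comfortably inside its asserted tolerance.
Degenerate inputs fail loudly everywhere: non-positive correlogram heads,
too-short fit windows, duplicate time stamps or saturation points,
infeasible packings, truncated trajectory frames (the error names the
frame), out-of-range RDF windows, and missing charge/LJ parameters (the
error lists the atoms).
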