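---
title: "Mean-force integration, binding thermodynamics and interface censuses for peptide dimerization"
author: "pgdimer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-force integration, binding thermodynamics and interface censuses for peptide dimerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgdimer)
```

## The problem

Cationic beta-hairpin antimicrobial peptides such as protegrin-1 kill
bacteria by assembling oligomeric pores in anionic membranes, and the dimer —
in either a parallel or an antiparallel beta-sheet packing — is the pore's
structural building block. A central thermodynamic question is *where*
dimerization is most favourable: in bulk water, on the membrane surface, or
inside the hydrophobic core. The standard computational answer is a potential
of mean force (PMF) `W(D)` along the peptide–peptide centre-of-mass
separation `D`, built from a series of restrained simulations, followed by a
Boltzmann integral that converts the profile into a relative binding constant
and a dimerization free energy, and an interaction census (ionic bridges,
hydrogen bonds) that explains the result mechanistically.

`pgdimer` implements that analysis chain as reusable, tested components, and
pairs it with a synthetic-data generator whose ground truth is known exactly,
so every stage can be validated quantitatively — something the original
cluster-scale trajectories (which are not publicly deposited) cannot offer.

## The model and its estimators

### Windowed mean forces

Each window holds the separation near a grid value `D` with a harmonic
restraint of stiffness 20 (kcal/mol)/Å² and records the instantaneous force
on the restraint springs every 0.2 ps. The window mean force is

> `Fbar(D) = -mean(F_res)` ,

the negated time average of the restraint force ([mean_force()]). Restraint
forces are strongly autocorrelated, so the naive standard error is far too
small. The package estimates the correlation time by a log-linear fit to the
normalized autocorrelation function ([autocorr_time()]) and the standard
error by block averaging ([block_sem()]): the series is cut into contiguous
blocks, and the spread of block means stabilizes once blocks are long
compared to the correlation time.

Numerical choices, made once and kept:

* **Autocorrelation fit window.** The fit uses lags up to the first zero
  crossing of the ACF, further truncated where the ACF falls below `1/e` —
  about one correlation time. An unweighted log fit that extends into the
  noise-dominated tail is strongly biased; restricting to the well-resolved
  decade keeps the estimator within a few percent of the AR(1) closed form
  `-dt/log(phi)` at the series lengths used here (checked at `phi` = 0.8 and
  0.98).
* **Block-size selection.** Block sizes double until the error estimate
  changes by less than 5% (plateau detection), with a floor of five
  correlation times per block and at least four blocks. The chosen size is
  reported with the estimate so the selection is auditable.
* **Biased ACF normalization.** The `1/n` normalization (as in `stats::acf`)
  is used for stability at large lags.
* **Burn-in.** Window records may discard an initial fraction
  (`burn_in`, default 0) — the emulated protocol equilibrates separately
  before production, so the default assumes a production-only record. Records
  much shorter than ~0.5 ns would make the block plateau unreliable; the
  per-window output carries `n_samples` and `tau` so such windows are visible.

### PMF by thermodynamic integration

The PMF is minus the integral of the mean force from infinite separation;
with windows only out to a finite distance the profile is anchored at the
largest simulated separation (25 Å by default, 27 Å when the plateau-check
window is present), where the profile has demonstrably flattened:

> `W(D_i) = sum over intervals [D_j, D_j+1] above D_i of h_j/2 (Fbar_j + Fbar_j+1)`

— the composite trapezoidal rule, exact for mean forces linear in `D` and
second-order accurate (`O(h^2)`) otherwise ([integrate_pmf()]). The anchor
value is exactly zero by construction; no explicit tail correction is applied
(the only supported correction is 0, matching the observed `< 1 kBT` residual
at 25 Å in this class of systems). Per-interval widths may differ, so the
9..25 Å grid plus a single 27 Å extension integrates without special casing.

Window simulations are statistically independent (they are separate runs), so
window errors propagate in quadrature through the trapezoid weights
([propagate_uncertainty()]):
`sigma_W(D_i)^2 = sum_j (w_j sem_j)^2`, with `w_j` the composite weight of
window `j` between `D_i` and the anchor. With the production-level window
error of 0.4 (kcal/mol)/Å uniformly on the nine-window grid this gives
`sigma_W(9 Å) = sqrt(4.8) ≈ 2.19` kcal/mol — the error bar grows toward
contact, as it must for a cumulative integral. Minima are located on the
grid with ties broken toward smaller `D` (deterministic output), flagged when
they sit on a grid edge, and optionally refined by a local parabola, reported
separately from the grid minimum.

### Binding constant and free energy

The relative, interval-normalized equilibrium binding constant over the bound
range `[Dmin, Dmax]` (defaults 9 and 25 Å: the contact distance `2a` of the
4.5 Å effective cylinder radius, and the separation where the profile has
plateaued) is

> `K = 1/(Dmax - Dmin) * integral of exp(-W(D)/kBT) dD` ,

and `dG0 = -kBT log K` at `T` = 310 K with `kB` fixed at 0.0019872041
kcal/(mol K). `W` is interpolated *linearly in W* between grid points —
bounded, monotone and convergent under refinement, unlike interpolating the
exponential itself. The Boltzmann factor of that piecewise-linear profile is
then integrated segment-wise in closed form (the exponential of a linear
function integrates exactly) on a refinement of at least 200 sub-points that
retains every profile knot. A plain trapezoid on `exp(-W/kBT)` was evaluated
and rejected: for wells tens of `kBT` deep its result still drifts by ~0.5–2%
between 200 and 400 sub-points, while the closed-form segment integral is
exact for the interpolation model and therefore refinement-stable for every
profile, including stepped ones. Window uncertainties propagate to `K` and
`dG0` by parametric bootstrap: window mean forces are resampled from
independent normals at their block-averaged errors and the whole chain is
re-evaluated ([binding_uncertainty()]).

No standard-state volume or symmetry corrections are applied: `K` is the
relative, interval-normalized quantity only, which is what the free-energy
differences between environments require.

### Interface census

On coordinate trajectories with a role topology the package counts:

* **Ionic bridges** between arginine guanidinium groups and chloride ions or
  anionic lipid head-group oxygens (hydroxyl, phosphate, ester, carbonyl).
  The per-frame distance of a pair is the minimum over the guanidinium
  heavy atoms (NE, CZ, NH1, NH2 by conventional naming; the set is
  configurable). Frames within 7.6 Å qualify as solvent-separated (SSSP),
  within 4.3 Å as direct contact (CSP); maximal consecutive runs of
  qualifying frames lasting at least 10 ps (inclusive frame count times the
  frame spacing; strict continuity by default, an optional 0–2 frame gap
  tolerance is off) become events. A run is tiered CSP when at least half its
  frames are within the contact cutoff; the per-frame contact counts are kept
  on each event so this majority rule is auditable, and census-level CSP/SSSP
  fractions are computed from the per-frame qualification, not the tier
  labels.
* **Hydrogen bonds** for donor-hydrogen/acceptor pairs strictly closer than
  2.4 Å — a donor-H-to-acceptor distance criterion with no angle term, the
  natural reading of a 2.4 Å cutoff. Bonds are *endogenic* when the atoms sit
  on the two different peptides of the dimer and *exogenic* when exactly one
  atom is peptide-bound; same-peptide and environment-environment pairs are
  ignored.

Census counts are time averages of *distinct* partners per frame: an ion
bridging several arginines counts once (the collective dimer census); a
`bridging_only` mode instead restricts to partners simultaneously in events
with both peptides, covering the stricter reading of "bound to both
peptides". Both cutoffs apply uniformly to chloride and oxygen partners, and
sub-persistence contacts are excluded from the averages, per the stated
10 ps rule. Distances are plain Euclidean: the synthetic fixtures are
unwrapped, and periodic-image handling is deliberately out of scope for
them.

## The synthetic-data generator

The generator emulates the two kinds of raw data the analysis consumes.

**Force records.** A `landscape` object fixes the true `W(D)` (flat,
harmonic well, square well with optional smooth tanh walls, or a tabulated
spline), anchored to zero at the top of its domain. Three fluctuation models
produce a window record at separation `D` with the restraint sign convention
`E[F_res] = +dW/dD`:

* `iid_gaussian` — white noise; the trivial calibration case.
* `ar1` — stationary AR(1) noise with lag-one coefficient `phi` and
  *stationary* standard deviation `sigma`, matching the closed forms the
  error machinery is tested against (`tau = -dt/log(phi)`,
  `SEM = sigma sqrt((1+phi)/(1-phi))/sqrt(n)`).
* `langevin` — the physically faithful model: overdamped Brownian dynamics of
  the separation coordinate on `W(x) + k_r/2 (x - D)^2`, recording the
  instantaneous spring force `k_r (D - x)`. Its stationary mean is the
  stiff-spring mean-force estimate (for a harmonic landscape exactly
  `k_r k (D - D0)/(k_r + k)`, i.e. the true mean force up to a factor
  `k_r/(k_r + k)` — 0.35% at the default well), and its fluctuation
  magnitude `k_r sqrt(kBT/k_eff)` and correlation time emerge from the
  physics rather than being prescribed.

Defaults mirror the production protocol where the protocol states them:
`dt` = 0.2 ps sampling, `k_r` = 20 (kcal/mol)/Å², `T` = 310 K, grid
9..25 Å in 2 Å steps. The diffusion coefficient of the coordinate is not
stated by any protocol quantity; it is fixed at 0.05 Å²/ps, giving a
spring-force correlation time of ~0.62 ps — several sampling intervals, so
the decorrelation machinery is genuinely exercised — at run lengths a laptop
handles. Only stationary statistics matter for validating the estimators;
kinetics are not modelled. Integration uses Euler–Maruyama with 10 substeps
per recorded sample (stationary-variance bias below 2%, verified against
`kBT/k_r` in the tests, and no bias in the stationary mean for linear
forces). Langevin sampling of a hard-edged square well is refused — the
gradient must exist everywhere — use `edge_width > 0`.

**Trajectories.** A `contact_schedule` places partner atoms at exact scalar
distances from target atoms (guanidinium reference atoms, donor hydrogens)
over half-open intervals `[start_ps, end_ps)`; `floor(duration/dt) + 1`
frames are emitted. Sites sit on a lattice hundreds of Å apart and
non-reference guanidinium atoms are offset perpendicular to every partner
approach axis, so the minimum group distance equals the scheduled scalar
*exactly* and unscheduled pairs are always beyond the solvent-separated
cutoff (idle partners rest at exactly `baseline_distance` from their anchor
site). The census uses distances only, so this deliberately non-physical
geometry is sufficient — and makes every expected census number computable by
hand. The half-open convention means a 12 ps interval at `dt` = 0.2 ps covers
exactly 60 frames (duration 12 ps, which passes the 10 ps persistence rule),
and an interval may end one frame past the trajectory to cover the final
frame.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: membrane and solvent degrees of freedom, restraint
coupling to specific backbone atoms, force correlation times of ~0.1 ns
(the synthetic correlation time is ~0.6 ps; the block-averaging machinery is
scale-free, but real records need proportionally longer windows), periodic
boundary wrapping, and any real dimer geometry. The synthetic landscapes of
the analysis scripts encode the *qualitative* environment ordering only;
their depths are not the study's values, because the study's profiles cannot
be recomputed without its trajectories.

## Study conditions and problem sizes used here

The packaged analysis (`analysis/` scripts, acceptance checks) runs the full
54-window design (plus the 27 Å extension, 55) with 4 ns window records
(20000 samples) for the worked study, and 1 ns records for the 20-seed
end-to-end validation study — sizes chosen so the whole analysis reruns in
seconds while leaving block-averaged errors at a few tenths of a kcal/mol/Å,
comparable to the production level of 0.4 (kcal/mol)/Å.

The end-to-end validation places a 5 kcal/mol parabolic well (centre 13 Å,
anchored at 25 Å — mean force linear in `D`, so the trapezoid is exact and
any recovery error is attributable to sampling alone), runs 20 independent
seeds of the full window pipeline, and checks that (i) the seed-averaged
profile lies within the `2 sigma_W` band quoted for a single run at every
grid point, (ii) the per-seed/per-point `|z| <= 2` coverage is at least 85%
(nominal 95%; a broken error model lands far below), and (iii) the pooled
`dG0` falls within three times its propagated uncertainty of the
error-function closed form. A literal "every seed, every point within
2 sigma" reading would fail by design about once per 20 clean runs — a 2-sigma
interval is a 95% interval — so the calibration is asserted at the level the
noise model supports.

## Degenerate inputs and tie-breaks

Constant force series return a zero correlation time with a warning flag and
a zero block error. Duplicate window separations are an error; unsorted
windows are sorted with a notice. PMF minima tie toward smaller `D`.
`K <= 0`, `Dmin >= Dmax`, bounds outside the profile span, mis-ordered census
cutoffs, unknown configuration keys and schedule conflicts (one partner at
two distances at once) are all hard errors with named offenders. An arginine
declared without guanidinium atoms is an error naming the residue.

## Known limitations

* The stiff-spring estimator is taken at face value (no umbrella
  reweighting): mean forces carry the `k_r/(k_r + k_eff)` attenuation and a
  displacement bias where the landscape curvature changes sharply. Both are
  well below the statistical error for the landscapes used here, but a very
  soft restraint or a cliff-edged landscape would need reweighting.
* Error propagation treats windows as independent; correlated window errors
  (e.g. shared equilibration artefacts in real data) would be underestimated.
* The census has no angle criterion for hydrogen bonds and no
  hydration-shell analysis behind the SSSP label — both deliberate, matching
  the distance-only definitions it implements.
* The cylinder model of the peptide enters only through `2a` = 9 Å as the
  default contact distance; the cylinder length is never needed by any
  implemented equation and is left symbolic.
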