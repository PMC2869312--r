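---
title: "Modeling receptor diffusion in a crowded post-synaptic density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling receptor diffusion in a crowded post-synaptic density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdcrowd)
```

## The model

AMPA-type glutamate receptors (AMPARs) diffuse laterally in the post-synaptic
membrane. The post-synaptic density (PSD) beneath that membrane is a dense,
essentially static scaffold of proteins; receptors moving through it collide
with those proteins and may transiently bind some of them. `psdcrowd`
implements a lattice Monte Carlo model of this process and asks how much of
synaptic receptor retention can be explained by *molecular crowding* alone —
steric obstruction, with no binding chemistry at all.

The membrane is a square mesh with toroidal (periodic) boundary conditions.
A single receptor occupies one lattice site; each time step `dt` it draws a
random axis and a random direction and attempts a move of one lattice
spacing. The spacing is tied to the free diffusion coefficient through the
mean squared displacement of unobstructed two-dimensional diffusion,
`MSD = 4 D t`:

    dx = sqrt(4 * D_free * dt)

With the defaults `dt = 1e-3` ms and `D_free = 0.200e-3` µm²/ms this gives
`dx = 8.9e-4` µm, so a 2 × 2 µm membrane spans 2236 × 2236 sites. All units
are fixed package-wide: ms, µm, and binding energies in k~B~T.

PSD molecules are immobile and occupy single sites; a fraction `C` of the
sites in a target region is occupied (*molecular crowding*). A move into an
occupied site is an elastic collision: the receptor returns to (i.e. stays
at) its original position. A fraction `P` of the PSD molecules may instead
bind the receptor on contact. While bound, the receptor unbinds each step
with probability `exp(-E)` (energy barrier `E` in k~B~T), making the mean
bound dwell `exp(E)` steps; since one step is 1 µs, this matches a 1/µs
attempt rate — e.g. at the top of the physiological range, `E = 13` k~B~T,
the expected dwell is `1e-6 / exp(-13) = 0.44` s. On unbinding the receptor
is released *isotropically*: it moves to a uniformly chosen unoccupied
neighbour of the binding site (rotational diffusion of the complex justifies
forgetting the approach direction). If all four neighbours are occupied, it
remains on the binding site, unbound, for that step.

Binding succeeds on every contact with a bindable site (the bounce
probability on contact is zero). This is the simplest reading consistent
with detailed balance — the equilibrium association of a site is then
proportional to `exp(E)`, which the test suite verifies against a
brute-force Markov-chain enumeration on a small torus. The companion
assumption, per-step unbinding probability `exp(-E)`, is pinned by the
dwell-time arithmetic above.

Walkers are strictly non-interacting; ensembles of hundreds of walkers over
one obstacle field stand in for repeated single-particle experiments.

## Analysis

- **Ensemble MSD** (`compute_msd`) is origin-referenced:
  `MSD(t) = mean_i |r_i(t) - r_i(0)|²` over unwrapped positions — the spread
  from the point of origin, not a sliding-window time average. Unwrapping
  uses per-axis winding counts across the torus.
- **Anomalous exponent** (`fit_alpha`): under obstruction
  `MSD = 4 D t^alpha` with `alpha < 1`; `alpha` is the least-squares slope of
  `log(MSD)` vs `log(t)` over a window. The default window starts at 10 ms
  to skip the early transient; the uniform-binding protocol fits a late
  window (from 500 ms) where the log-log curve has become linear again.
  Both windows are arguments.
- **Apparent diffusion coefficient** (`compute_dapp`):
  `D_app = |r(t_obs) - r(0)|² / (4 t_obs)` per walker — what an observer
  infers from a displacement after a set time. At `C = 0` the squared
  displacement is exponentially distributed, so the median is
  `ln(2) * D_free = 0.1386e-3` µm²/ms, which is also the experimentally
  reported median for extra-synaptic AMPARs. The observation time is a
  choice of the observer; the package default is `t_obs = 1000` ms (the
  trapping-experiment horizon). Under anomalous diffusion `D_app` decays
  with `t_obs`, so this choice materially affects crowded-membrane values —
  it is exposed as an argument everywhere.
- **Kusumi confinement fit** (`fit_kusumi`): the confined-diffusion model
  `MSD = (L²/3)(1 - exp(-10 D t / L²))` is fitted over `L` by
  Levenberg–Marquardt least squares with `D` fixed at `D_free` (under the
  corral interpretation the within-compartment coefficient equals the free
  one). `L` is initialized at `sqrt(3 max(MSD))`, its value for a fully
  saturated curve.
- **Closed-form calculators**: `residence_time` inverts
  `distance = sqrt(4 D t^alpha)` for the time to reach a PSD boundary;
  `kd_to_kbt` converts dissociation constants (`RT = 2.479` kJ/mol at 298 K,
  2.5 kJ/mol per k~B~T); `unbind_time`, `psd_mass_fraction` and
  `occupied_volume_fraction` reproduce the crowding arithmetic. Note the
  occupied-volume formula yields ≈ 0.39 for 10,000 × 100 kDa molecules in
  3.06e6 nm³; the function returns the formula value.

## The in-silico experiments

Five protocols orchestrate these pieces (all deterministic given a master
seed; every obstacle field, start-site draw and walker stream is derived
from it):

1. `run_alpha_sweep` — whole-membrane random fields over a grid of `C`;
   produces the sigmoidal `alpha(C)`: free diffusion below `C ≈ 0.3`, a
   steep drop over `0.3–0.5`, arrest above. The steepness is a percolation
   phenomenon: free sites fail to percolate once the obstacle fraction
   crosses ≈ 0.41 on the square lattice.
2. `run_trapping_experiment` — a centered 0.5 µm PSD on a 1 × 1 µm torus,
   obstacles only inside the PSD, receptors released inside, position
   queried at 1 s. At `C = 0` the retention equals the PSD's area fraction
   (0.25); above `C ≈ 0.6` receptors stay confined.
3. `run_binding_fraction_sweep` — crowded membrane (`C = 0.45`) with a
   fraction `P` of molecules bindable at energies uniform on 4–8 k~B~T;
   binding paradoxically *mobilizes* receptors (isotropic release lets them
   pass positions that pure obstacles forbid).
4. `run_uniform_binding_sweep` — all molecules bindable at one energy `E`;
   diffusion is transiently anomalous, then normal with a reduced
   prefactor, the crossover time growing with `E`.
5. `run_stimulation_experiment` — a 500/100/700 ms timeline in which a
   stimulus makes a random 10% of the PSD molecules bindable at energy `E`;
   reports the percent change of the mean PSD-resident count between the
   first and last 400 ms. Strong binding accumulates receptors.

Obstacles cover the whole membrane in protocols 1, 3 and 4 and only the PSD
interior in 2 and 5, following each experiment's geometry. In protocol 5
the stimulated molecules share one energy per run, and at stimulation end
bound receptors are released isotropically at once.

## Design choices on genuinely open points

- **One field per ensemble.** Whether obstacle fields are resampled per
  walker is unspecified; the package draws one field per ensemble and
  resamples across replicate ensembles (replicate seeds), which makes
  field-realization variance visible rather than silently averaged.
- **Walker count defaults**: 400 for sweeps and trapping, 500 for the
  stimulation protocol (its figure legend), with 1000 available — all
  arguments.
- **Site membership** is by site centre with half-open rectangles, so
  adjacent regions tile exactly and the 0.5/1.0 µm geometry contains
  exactly one quarter of the sites.
- **Obstacle counts are exact** (`round(C * n_sites)` drawn without
  replacement), not per-site Bernoulli — removes occupancy variance between
  seeds so `alpha(C)` curves are comparable.
- **Regular arrangement**: pure sublattices only realize densities `1/p²`,
  so intermediate `C` uses a periodic block pattern (`(i mod p) < q` on both
  axes) with density `(q/p)²` closest to the target. Either way the pattern
  is deterministic, and obstruction without randomness yields tortuosity,
  not anomaly.
- **RNG**: each walker owns a counter-derived xoshiro256+ stream
  (splitmix64-seeded from master seed and walker index), with a fixed draw
  order (axis, direction, release) per step. Trajectories are bit-exactly
  reproducible and independent of scheduling, and protocol phases continue
  streams under distinct offsets.

## Numerical scales used in the shipped tests

Unit tests run on a reduced lattice with `dt = 1` ms and `D = 0.25` µm²/ms
so that `dx = 1` µm and lattice indices equal physical coordinates; the
obstruction physics is scale-free, so regime structure survives the
reduction. Two caveats discovered while scaling: confinement is a boundary
phenomenon, so a trapping PSD must span many sites (the reduced trapping
test uses a 100-site PSD); and binding-assisted mobility requires the bound
dwell `exp(E)` steps to be much shorter than the run, so the reduced
binding test uses 2–4 k~B~T over 2000 steps. The acceptance-level tests and
`scripts/acceptance.R` run the full published conditions (2 × 2 µm, 400–500
walkers, 1–2 simulated seconds, ~10⁹ steps per protocol cell).

## What the synthetic fixtures do and do not show

`make_gaussian_walk_fixture` produces off-lattice Gaussian walks with known
`D` — an exact realization of normal diffusion used to validate the
estimators independently of the lattice engine. `make_powerlaw_msd_fixture`
evaluates `4 D t^alpha` noise-free, so `fit_alpha` must recover `alpha` to
machine precision. Passing these shows the *estimators* are correct; it
says nothing about whether real PSDs are in the crowded regime, which is an
empirical question the simulation protocols only parameterize.

## Known limitations

- The bounce probability on contacting a bindable molecule is fixed at
  zero; only its companion unbinding law is pinned by independent
  arithmetic. The sign of the weak-stimulation (2 k~B~T) net flux is
  sensitive to this choice.
- Apparent diffusion coefficients under crowding depend strongly on the
  observation time, which has no canonical value; comparisons across
  studies must match `t_obs`.
- Confinement lengths fitted just below the percolation threshold
  (`C ≈ 0.38–0.41`) are steeply sensitive to `C` and to run duration;
  treat absolute values there as order-of-magnitude.
- PSD molecules are static, single-site, and non-interacting with each
  other; receptor recycling (exo/endocytosis), receptor–receptor
  interaction, and non-rectangular PSD shapes are out of scope.

## A minimal session

```{r example, eval = FALSE}
cfg <- make_config(width = 2, height = 2, duration = 2000,
                   n_walkers = 400, seed = 1)
fld <- make_obstacle_field(cfg, C = 0.40)
ens <- simulate_ensemble(cfg, fld)
msd <- compute_msd(ens)
fit_alpha(msd)
fit_kusumi(msd, cfg$D_free)
```
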