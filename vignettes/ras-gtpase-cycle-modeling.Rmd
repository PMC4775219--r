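---
title: "Modeling the Ras GTPase cycle: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the Ras GTPase cycle: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rascycle` models a minimal signaling system reconstituted in vitro: a small
GTPase (Ras) on a bead surface, driven by a nucleotide exchange factor (GEF),
deactivated by GTPase-activating proteins (GAPs), and read out through the
recruitment of fluorescent effector domains that bind only the active,
GTP-loaded form. This vignette explains the models the package implements,
the output statistics computed from them, the synthetic-data generator used
in place of microscopy data, and the numerical and design choices made where
more than one reasonable option existed.

## The GTPase cycle models

Time is in seconds and concentrations in nM throughout; bimolecular rate
constants are nM⁻¹s⁻¹. GEF is never an explicit enzyme in the constitutive
models: its activity is folded into the first-order nucleotide-release rate
on Ras·GDP, `k_exch = k_per_gef × [GEF]`, with `k_per_gef = 5e-6 nM⁻¹s⁻¹`
(so 1 µM GEF gives 0.005 s⁻¹). All networks are simulated as deterministic
mass-action ODE systems.

**Two-state model** (`build_two_state_model()`). Ras alternates between GDP-
and GTP-bound states through the reactions

```
G + T  -> GT         k_nt_on   = 1          (nucleotide binding)
GT     -> GD         k_hyd × gap_level      (lumped GAP deactivation)
GD     -> G + D      k_exch    = 0.05       (GEF-driven exchange)
GT + EFF <-> GT_EFF  1e-4 / 1e-3            (effector binding, Kd = 10 nM)
GT_EFF -> GD + EFF   k_hyd_eff = 1e-4       (hydrolysis under the effector)
```

`G` is the transient nucleotide-free state; `T`/`D` are free GTP/GDP, with
GTP supplied at an effectively infinite 10⁵ nM. GAP activity appears only as
a multiplier on the deactivation rate, so this model cannot distinguish GAP
binding from GAP catalysis.

**Competition model** (`build_competition_model()`). GAP becomes an explicit
species that competes with the effector for active Ras and commits it to
hydrolysis:

```
GT + GAP <-> GT_GAP  1e-4 / 1e-2
GT_GAP -> GD + GAP   k_gap_cat = 1
```

with intrinsic hydrolysis (`GT -> GD`, 1e-4) alongside and `k_exch = 0.005`.
Whether this model can overshoot depends on the GAP kinetics: with
physiologic parameters (`k_off = 0.01, k_cat = 1`) the response is monotone
at every GAP level, while a slow-release/slow-catalysis parameter set
(`k_off = k_cat = 1e-4`) turns GAP into a stoichiometric trap and produces
overshoot at high GAP. `gap_preset()` provides these pairs plus NF1-like
(0.01/0.1) and p120-like (0.25/0.4) presets.

**Three-state model** (`build_three_state_model()`). Adds a post-hydrolysis
state `GI` that is refractory to GEF action and relaxes back to ordinary
Ras·GDP slowly (`GI -> GD`, `k_gi_reset = 1e-4`). A step input now produces
a transient: the initial GD pool is activated in a burst, GAP-driven
hydrolysis funnels it into `GI`, and the output decays toward a low
nonequilibrium steady state set by the slow reset. At canonical conditions
(10 nM Ras, 50 nM effector, 1 µM GEF) the transient score is ≈ 0.82 at 1 µM
GAP and ≈ 0 without GAP.

### Which hydrolysis channels produce the refractory state

The model family leaves open which hydrolysis channels route through `GI`.
Routing *all* channels (intrinsic, GAP-catalyzed, effector-bound) through
`GI` makes even GAP-free responses overshoot with score ≈ 0.44 on the slow
`k_gi_reset` timescale, which contradicts the monotone low-GAP behavior the
system family is meant to reproduce. The package therefore routes **only
GAP-catalyzed hydrolysis** through `GI` by default; the per-channel flags
`route_intrinsic`, `route_gap`, `route_effector` expose the alternatives.
With this default the model shows a monotone response in low-GAP networks
and a transient response in high-GAP networks, which is the qualitative
dichotomy of interest.

### Mutants and effectors

`apply_mutant()` scales three things: GAP-stimulated catalysis
(`gap_cat_factor`), intrinsic hydrolysis in both the free and effector-bound
channels (`hyd_factor`), and the effector off-rate
(`effector_affinity_factor`). The oncogenic G12V default is `(0, 1, 1)`:
GAP catalysis abolished but GAP *binding* retained, so the mutant still
sequesters GAP. The intrinsic-rate change of real G12V is not separately
encoded because GAP-free wild-type and mutant outputs are nearly identical
in this regime; `hyd_factor` is exposed for sensitivity analysis.

`add_effector()` attaches any number of named effectors that compete for
the same active Ras pool (active Ras binds at most one partner). Kinetic
asymmetry between effectors is enough to encode different temporal outputs
from one input: with 1 µM GAP, a c-Raf-like effector (`k_off = 1e-3`)
responds transiently while a B-Raf-like one (`k_off = 2.5e-4`) responds in
a sustained way, and three effectors with staggered on-rates, off-rates and
concentrations produce an ordered sequence of output peaks.

## Positive feedback architectures

The two feedback designs are the package's own minimal mechanistic
encodings of verbally described architectures; every constant is exposed
and none is a measured value.

**Recruitment feedback** (`build_recruitment_feedback_model()`). A GEF
fused to a Ras-binding domain accumulates on the surface in proportion to
active Ras. Arm binding is treated as a rapid 1:1 equilibrium between total
GEF `G` and the active pool `A = GT + Σ GT_EFF` (GAP-bound Ras is committed
and recruits nothing): the bound amount `B` is the smaller root of
`B² − (A+G+Kd)B + AG = 0`, and the exchange rate becomes

```
k_exch(x) = k_per_gef × ((G − B) + alpha × B)
```

An earlier design carried the arm-bound species explicitly; because those
species were protected from GAP they escaped the refractory trap and made
the feedback benefit *grow* with GEF, inverting the expected structure of
the gain surface. The rapid-equilibrium rate law avoids both sequestration
artifacts: at saturating GEF the bound term is capped by the active pool
(`B ≤ A`), so feedback adds nothing once the constitutive system is strong,
and the gain surface decreases along the GEF axis. Defaults: c-Raf-like arm
kinetics (Kd = 10 nM) and `alpha = 5000`, chosen so that a 20 nM GEF / 1 µM
GAP network gains visibly (gain ≈ 1.9) while a 2 µM GEF / GAP-free network
is unchanged (gain ≈ 1.01). With GAP-routed refractory recycling the
attainable low-GEF gain is intrinsically bounded (≈ 2): at long times the
`GI -> GD` reset step, not exchange, limits throughput, so recruitment
mainly accelerates consumption of the initial GD pool.

**Allosteric feedback** (`build_allosteric_feedback_model()`). Active Ras
binding to a distal site stimulates the GEF itself:

```
k_exch(x) = k_basal + (k_max − k_basal) × GT_tot / (K_A + GT_tot)
```

with `GT_tot = GT + Σ GT_EFF + GT_GAP`, `k_basal = 0.1 × k_max` and
`K_A = 5 nM` by default. A step in GEF *protein* is thereby converted into
a ramp in GEF *activity*: activation desynchronizes, the initial burst that
drives the refractory overshoot shrinks, and the high-GAP transient score
drops (0.82 → 0.71 at canonical conditions). The constitutive system run at
`k_max` bounds the allosteric output pointwise only in the monotone
(GAP-free) regime; under overshoot the constitutive trace decays while the
ramped one is still rising, so the bound is tested where it is meaningful.

## Output features

All features operate on a `timecourse` (times + values). Definitions were
chosen as the simplest ones consistent with their verbal descriptions, and
each knob is exposed:

* `integrated_signal()` — trapezoidal integral over the full span.
* `initial_rate()` — least-squares slope over the points up to the first
  crossing of 10% of the peak (minimum 3 points).
* `transient_score()` — `(peak − final)/peak` clipped to [0, 1], with
  `final` the mean of the last 3 samples for noise robustness. 0 means
  monotone rise; 1 means full decay back to baseline.
* `pulse_width()` — interpolated time spent above `(peak + final)/2`.
* `distortion_score(mutant, wt)` and `feedback_gain(fb, base)` — ratios of
  integrated signals on a shared time grid; both are invariant to a common
  linear gain, so they can be computed on fluorescence as well as on nM.

## Phase diagrams and isoclines

`run_config_grid()` runs one simulation per (GEF, GAP, density)
configuration; the default grid is 4 GEF levels {20, 200, 1000, 2000} nM ×
4 GAP levels {0, 10, 100, 1000} nM × the 6 canonical density bins = 96
configurations (≈ 40 s on one CPU). Density maps to total Ras at 250
molecules·µm⁻² per nM, tying the typical bead loading of 2500
molecules·µm⁻² to the canonical 10 nM Ras. `interpolate_phase()` builds a
bilinear surface in (log₁₀ GEF, log₁₀(GAP + ε)) with ε = 0.1 × the smallest
nonzero GAP level, exact at the nodes; `extract_isocline()` returns
marching-squares contours — neutral paths along which different network
configurations produce the same output. Integrated signal increases with
GEF and decreases with GAP across the grid, with one caveat: at the highest
exchange rates the early burst feeds the refractory trap slightly faster,
so the GEF axis can dip by ≲ 1% past saturation.

## Ras surface density estimation

`density_calibration()` carries the two printed constants — 4.287 µM·AU⁻¹
(solution calibration of labeled Ras) and 602 molecules·µm⁻³ per µM with a
55 nm confinement length, giving 33.11 molecules·µm⁻² per µM (33.1 as
printed; the product is implemented verbatim even though "radius of
confinement" vs. confinement height is ambiguous in the source protocol).
Bin assignment to the canonical centers {150, 300, 600, 1200, 2500, 10000}
is nearest-in-log₂ with ties to the lower bin: the bins are ≈ 2× spaced, so
linear nearest-distance would swallow the wide lower shoulder of the 10000
bin. This estimate is deliberately crude; only relative densities matter
downstream.

## The synthetic-data generator

`sample_beads()` + `render_traces()` stand in for the microscopy pipeline.
What they emulate:

* per-bead densities lognormal around each canonical bin (log-sd =
  `cv_bead`, default 0.2);
* bead radii uniform in 20–40 px, so areas (1 257–5 027 px) sit inside the
  400–15 000 px particle filter;
* ground-truth effector occupancy simulated per bead with total Ras scaled
  from its density;
* observed AU = `gain × occupancy × bead_factor + background + N(0, σ)`,
  with a lognormal per-bead factor and Gaussian per-timepoint noise
  (defaults 100 AU/nM, 50 AU, 5 AU);
* 15-min sampling over 42 000 s, and full determinism under the seed.

The defaults were calibrated once so that a 15-bead bin average has a
median post-onset SEM/mean comfortably below 15% (measured ≈ 8–9%), the
stated precision of the experimental traces. What the generator does *not*
emulate: photobleaching, stage drift, uneven illumination, bead overlap,
and any intensity distribution other than lognormal (an assumption, made
explicit here). Passing pipeline tests on synthetic data therefore
demonstrates correctness of the processing arithmetic, not robustness to
those real-world artifacts.

`render_image_series()` renders the beads as non-overlapping uniform disks
in a two-channel 16-bit stack (static GTPase channel, time-varying effector
channel) for exercising the particle detector; `emit_log_format()` writes
the measurement-log dialect (`area,ras_mean,perim,` header line, one
measurement line per timepoint, `!` stop marker per bead) that
`parse_bead_log()` reads back losslessly.

## The trace pipeline

`normalize_trace()` divides by the bead perimeter (the signal is a surface
ring in the confocal slice) and zeroes the t₀ value, which also removes any
constant background; both channels are treated identically.
`bin_and_average()` converts the Ras channel to density, assigns the
canonical bin, and averages the normalized traces pointwise with
SEM = sd/√n. `detect_beads()` thresholds (Otsu by default), labels
8-connected components, drops border-touching components, and filters by
area ∈ [400, 15000] px and circularity `4πA/P²` ∈ [0.60, 1.00], with the
perimeter taken from the polygonal chain contour and circularity capped at
1 (rasterized disks would otherwise exceed it).

## Numerical choices

* **Integration**: `deSolve::lsoda` with rtol 1e-8 / atol 1e-12 nM. The
  nucleotide-binding step (1 nM⁻¹s⁻¹ against 10⁵ nM GTP) makes the system
  stiff by design; this is documented, not softened.
* **Cross-check**: `euler_simulate()` is an independent fixed-step explicit
  Euler integrator (C++) for pure mass-action networks. Explicit Euler
  needs `dt` below ~2/λ for the fastest pseudo-first-order rate λ; at the
  canonical 10⁵ nM GTP that means dt < 2×10⁻⁵ s, so equivalence checks run
  at 10³ nM GTP and dt = 5×10⁻⁴ s, where the two integrators agree to ~10⁻⁷
  relative (asserted at 10⁻³).
* **Steady state**: integration in 42 000 s chunks until max |dx/dt| <
  10⁻⁹ nM/s over all species *except* free T and D — the cycle burns GTP
  at steady state, so the infinite nucleotide reservoir drifts forever by
  design — with a hard cap of 10 × 42 000 s.
* **Quadrature bias**: with a 15-min grid the sharp high-GAP peak sits
  inside the first interval, biasing the trapezoidal integral by ≈ 5%
  relative to a 10 s grid; ratio features (distortion, gain) are taken on
  matching grids, so the bias largely cancels.
* **Two-state monotonicity**: randomly parameterized two-state systems can
  show relative dips of order 10⁻⁴ (confirmed against the Euler
  integrator, so not an artifact); "no overshoot" is therefore asserted as
  transient score < 10⁻³, far below any observable transient.
* **Tie-breaks**: density bin ties go to the lower bin; degenerate
  (constant) phase surfaces yield no isoclines.

## Problem sizes

The test suite and acceptance script use the canonical 42 000 s horizon at
15-min sampling for single runs, the full 96- and 16-configuration scans,
90-bead synthetic datasets (15 per bin), 100-draw property sweeps, and
3 600–4 200 s horizons for Euler cross-checks; the whole suite runs in
about a minute on one CPU.

## Known limitations

* No spatial effects: membranes, diffusion, nanoclustering and bead-surface
  geometry are outside the model family, which is well-mixed by
  construction.
* No stochastic (Gillespie) simulation; copy numbers on a bead are large
  enough that deterministic kinetics is the intended regime.
* Thermodynamic cycle closure is not enforced; rate constants are taken as
  printed, and the models are driven, open systems.
* The feedback rate laws are minimal encodings of verbal mechanisms; their
  constants are tuning parameters, and only the qualitative claims about
  gain structure should be read from them.
* The density estimate is a calibrated approximation; absolute molecule
  counts should not be quoted from it.
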