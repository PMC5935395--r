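---
title: "A minimal continuous model of 3-D flocking: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal continuous model of 3-D flocking: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flock3d)
```

## The model

`flock3d` simulates `N` identical self-propelled agents moving in a cubic box
of side `L` with periodic boundaries in all three directions. Agent `i` has
position $\mathbf{r}_i(t)$ and velocity $\mathbf{v}_i(t)$, and obeys

$$
m \frac{d\mathbf{v}_i}{dt}
 = \frac{m}{\tau}\,\bigl(v_0 - |\mathbf{v}_i|\bigr)\,
   \frac{\mathbf{v}_i}{|\mathbf{v}_i|}
 \;+\; \sum_{j \ne i} \frac{c}{r_{ij}^2}\,\hat{\mathbf{r}}_{ij}
 \;+\; \boldsymbol{\xi}_i(t),
$$

with three ingredients and nothing else:

1. **Speed control.** Each agent relaxes its *speed* toward a preferred
   value `v0` with time constant `tau`, along its *own* heading. There is no
   explicit velocity-alignment term; the force vanishes at `|v| = v0`,
   accelerates slower agents and brakes faster ones.
2. **Radial repulsion.** Pairs closer than the cutoff `R` repel with the
   central inverse-square force `c / r^2` (collision avoidance). Distances
   are always minimum-image distances; pairs at `r >= R` (strictly) do not
   interact.
3. **Effective attraction.** The periodic box keeps the group together; no
   explicit attraction force exists.

Noise (amplitude `xi`) and a uniform interaction delay `t_d` are optional
disturbances, described below. Units are SI throughout; the reference
parameter set is `N = 200`, `L = 50` m, `v0 = 5` m/s, `tau = 1` s,
`m = 1` kg, `c = 1` N m², `R = 10` m, `dt = 1e-3` s (`model_params()`).

The point of the model is that these three ingredients suffice for stable
spatial ordering of the whole group, that the resulting order-disorder
transition is rapid and hysteretic under noise, and that delayed
interactions act very differently from noise.

## Order parameter

Overall ordering is measured by the *efficiency*

$$E(t) = \frac{1}{N v_0}\Bigl|\sum_i \mathbf{v}_i(t)\Bigr|,$$

which is 1 for perfect alignment at the preferred speed,
$\mathcal{O}(N^{-1/2})$ for independent random headings (≈ 0.065 at
`N = 200`), and deliberately *not clamped*: it may exceed 1 when many agents
move faster than `v0`. Ensembles of runs are summarized by histograms of
`E` over ratio-spaced times (ratio $10^{1/30}$, bin width 0.01) and by the
Binder cumulant

$$B(E) = 1 - \frac{\langle E^4 \rangle}{3 \langle E^2 \rangle^2},$$

computed with plain arithmetic means (no bias correction: the statistic is
defined through ensemble moments, and at ensemble sizes of hundreds of runs
the corrections are negligible). `B` is 2/3 for a sharp distribution, 0.4
for samples uniform on [0, 1]; tracked against system size (normalized
variant `B/N`) it diagnoses whether the transition stays bimodal, i.e.
discontinuous.

## Integration

The production integrator (`run_sim()`, compiled) is the classical explicit
midpoint method. Writing `F(s)` for the deterministic force field evaluated
on a full state `s`:

1. `F1 = F(state_t)`;
2. half-step state at `t + dt/2`: velocities `v + F1 dt/(2m)` (plus a noise
   impulse over `dt/2`), positions `r + v dt/2`;
3. `F2 = F(half-step state)`;
4. update `v <- v + F2 dt/m` (plus a noise impulse over `dt`) and
   `r <- r + v_half dt`, wrapped into the box.

Positions advance with the *half-step* velocities (the textbook midpoint
variant). For a single agent the scheme reproduces the closed-form speed
relaxation `v(t) = v0 + (v(0) - v0) e^{-t/tau}` with global error
$\mathcal{O}(\Delta t^2)$, which the test suite verifies, together with the
4-fold error reduction on halving `dt`. Two-agent encounters (below) use
forward Euler instead, whose first-order error is directly controlled by the
`dt_convergence()` experiment. Velocities are never bounded; positions are
wrapped every step. A non-finite state aborts the run with the step index,
and exactly coincident agents (where the repulsion diverges) are a hard
error — the initializer makes them impossible at `t = 0`.

### Noise convention

The noise term is a random *force* of constant magnitude `xi` whose
direction is re-drawn uniformly on the sphere, independently for every agent
and every update — uncorrelated in time and among agents. Over an update of
length `h` it contributes a velocity impulse of magnitude `xi * h / m`:
`xi * dt` for the full update and `xi * dt/2` for the first half-step
(`noise_scaling = "linear"`, the default). Under this convention the free
agent's velocity variance grows at rate `xi^2 dt / m^2`, i.e. the effective
diffusion depends on the step size — that is a property of the model
definition (a constant-magnitude force re-oriented every step), not an
integration artifact.

Because a step-size-independent formulation is the natural alternative, the
package also provides `noise_scaling = "sqrt"`, where the impulse is
`xi * sqrt(h) / m` and the diffusion rate `xi^2/m^2` is `dt`-free. The two
conventions coincide at `dt = 1` and differ by a factor `sqrt(dt)` otherwise;
all noise experiments state which convention they use. We chose "linear" as
the default because the half-step/full-step impulse pair (`xi dt/2`,
`xi dt`) is internally consistent only under it, and because under it the
interesting noise amplitudes sit at the scale where per-step impulses are
comparable to the per-encounter alignment gain, which is the marginal regime
the hysteresis experiment probes. Noise is injected by the integrator as
velocity increments; it is *never* routed through the delay buffer (delaying
an i.i.d. draw is statistically indistinguishable from not delaying it).

### Delayed interactions

A delay `t_d = k dt` (exact integer multiple, enforced at construction)
replaces the deterministic forces used in both midpoint stages by the values
of the same forces evaluated `k` steps earlier: two ring buffers (one per
stage) store the freshly evaluated `F1` and `F2` of every step, and the
update consumes the records from `k` steps back. The self-propulsion force
is part of the delayed record, so an agent's response to its own speed
changes is delayed too. During warm-up — the first `k` steps of any run,
including runs started from an equilibrated ordered state at `t = 0` — the
oldest available record is used (clamped lookup, counted and reported as
`n_clamped`); this avoids a discontinuous force onset, and the warm-up is
a `k dt ≤ 50` ms transient in runs of thousands of seconds. With `k = 0`
the buffered path is *bitwise identical* to the plain path, which the test
suite asserts.

### Neighbour search

Interacting pairs are found with a periodic cell grid: `floor(L/R)` cells
per side (cell side `L/floor(L/R) >= R`, so the grid tiles the box exactly
and the own-plus-26-neighbour-cells search is exhaustive). `model_params()`
rejects configurations with `floor(L/R) < 3`, where adjacent-cell search
could wrap onto itself. The reference box (`L = 50`, `R = 10`) gives 5³
cells of side exactly 10 m. `neighbor_pairs()` is validated against an
O(N²) all-pairs scan on 200 seeded configurations.

Inside the compiled integrator the pair search uses a *candidate list with
a skin*: all pairs within `R + skin` (default skin 0.5 m) are enumerated,
and the list is rebuilt whenever the two largest accumulated displacements
sum to more than half the skin — long before any outside pair could have
entered the true cutoff. The exact cutoff `R` is applied at every force
evaluation, so the force field is identical to a fresh-search
implementation; the skin only changes how often the enumeration runs
(roughly every 25-50 steps at `v0 = 5` m/s, `dt = 1e-3` s). Results are
therefore independent of `skin`, which is purely a throughput parameter.

## Initial conditions

Both initializations place agents uniformly at random, sequentially
rejecting any candidate closer than `0.6 L N^{-1/3}` (minimum-image metric)
to an already placed agent — at the model's densities the exclusion spheres
fill a few percent of the box and rejections are rare. All speeds start
exactly at `v0`.

* **Disordered** (`init_disordered()`): headings i.i.d. uniform on the
  sphere; `E(0)` is $\mathcal{O}(N^{-1/2})$.
* **Ordered** (`init_ordered()`): one shared random heading (`E = 1`
  exactly), then a noiseless, delay-free equilibration run so the spatial
  structure relaxes, after which the clock is reset to `t = 0`. The
  reference protocol equilibrates for 1e5 s; desk-scale experiments in this
  package use proportionally shorter intervals (stated per experiment).
  During equilibration the efficiency typically dips slightly below 1 while
  positions rearrange toward their caged, near-crystalline arrangement, and
  recovers — the dip is physical (directional order traded briefly for
  spatial order), not an error.

## The two-agent encounter experiment

The microscopic alignment mechanism is probed by a symmetric scattering
experiment (`run_encounter()`): two identical agents whose states remain
mirror images throughout. The geometry is parametrized by the distance `d`
between the two parallel planes containing the initial velocities and the
angle `phi` between the velocities; viewed along the plane normal the agents
start 1000 m apart and integration stops when that projected separation
reaches 1100 m. The encounter uses `v0 = 1` m/s, `tau = 1` s, `c = 1` N m²,
no noise, *no cutoff and no periodic box* — at separations of a kilometre a
10 m cutoff would simply switch the interaction off, and the experiment
isolates one pair in open space.

One realization choice deserves a note: "mirror images with respect to the
center of mass" cannot mean point reflection through the midpoint, because
that configuration has total momentum identically zero at all times and
could never show the momentum growth the experiment measures. The symmetry
realized here is the half-turn about the axis through the center of mass
parallel to the mean motion (equivalently, reflection through the plane
halfway between the two velocity planes combined with reflection through
the plane spanned by the mean-motion and plane-normal axes): agent 1 at
`(-D0/2, 0, +d/2)` with velocity `v0 (sin φ/2, cos φ/2, 0)`, agent 2 at
`(+D0/2, 0, -d/2)` with velocity `v0 (-sin φ/2, cos φ/2, 0)`. This is the
unique symmetric geometry with two parallel velocity planes a distance `d`
apart, projected separation `D0` and enclosed angle `phi`, and it keeps the
total momentum on the mean-motion axis, so the momentum change `delta_I`
reduces to a signed scalar. The integrator preserves the symmetry to
round-off (asserted below 1e-9 relative error along the whole trajectory).

The headline observable is `delta_I`, the change of `|p1 + p2|` between
start and stop: positive means the pair departs more aligned than it
arrived. Scanning `phi` at fixed `d` locates a threshold angle — about
40-50° for plane separations of a few metres — above which encounters align
(`threshold_angle()`, coarse scan plus bisection; ties broken toward the
upper bracket end, and a missing sign change in the bracket is an error
that reports `delta_I` at both ends). `dt_convergence()` quantifies the
Euler error by re-running sampled `(d, phi)` points at two step sizes; at
`dt = 1e-4` vs `1e-5` the maximal `delta_I` discrepancy is of order 1e-4,
well below the 1e-3-scale `delta_I` values themselves, so desk-scale scans
may use `dt = 1e-4`. The scan range of `d` (default 1-10 m) is
configuration, not a model constant.

## Experiment drivers and problem sizes

`order_transition()`, `noise_hysteresis()` and `delay_sweep()` package the
macroscopic protocols with seed management, per-run provenance (seed,
parameter signature) and failure isolation; `experiment_spec()` carries the
conditions and warns when a spec implies more integration work than a
desk-scale budget. "Tail E" of a run is the mean efficiency over the final
10% of the horizon — the model's own summaries are qualitative ("E ≈ 1" vs
"E ≪ 1"), so a fixed averaging window is our choice, as are the
classification thresholds: ordered above 0.8, disordered below 0.3, the gap
reported as undecided.

The reference ensembles (hundreds of runs to t = 1e6 s at dt = 1e-3) are
cluster-scale. This package ships and tests *desk-scale* presets chosen
once: `N = 50` agents at the reference density (`N/L³ = 0.0016` m⁻³, so
`L = 31.498` m), horizons of 1e3-1e5 s, and 3-5 seeds per condition. At
this scale, measured on this package:

* disordered starts at `xi = 0` complete their transition to `E > 0.9` at
  `t ≈ 2-6e4` s (seed-dependent, abrupt once started), so horizons of 1e4 s
  capture only the early growth of order, and full-ordering demonstrations
  use horizons of 5e4-1e5 s;
* the noiseless ordered state is indefinitely stable, and small interaction
  delays do not destroy it;
* the ordered state's robustness to noise is much weaker at `N = 50` than
  the reference-scale hysteresis suggests: each agent's heading decoheres
  under sustained noise (one-shot perturbations up to 0.1 m/s are fully
  stable, so this is not an integrator artifact), and at this density the
  repulsive caging re-aligns only weakly. Amplitudes of `xi ~ 0.2` and
  above destroy an equilibrated ordered state within 1e4 s, while
  `xi ~ 0.1` preserves it over 8e3 s without decisively blocking the
  emergence of order — the desk-scale window between "prevents ordering"
  and "destroys order" is marginal at best, and the test suite records
  this honestly (its non-triviality contrast fails). Conclusions about the
  reference-scale noise window should not be drawn from desk-scale runs.

What the synthetic experiments do *not* emulate about real flocks: agents
are point-like and identical, interactions are isotropic with a sharp
cutoff, noise is white and isotropic, and delays are uniform across agents
and effects. Passing tests therefore validate the model's internal
contracts (forces, integration, observables, protocols), not biological
realism.

## Degenerate inputs and tie-breaks

* `|v| = 0`: the propulsion direction is undefined; the force is zero (any
  fixed direction would break isotropy). The event has measure zero.
* Coincident agents: hard error (repulsion diverges); excluded at `t = 0`
  by the minimum-distance placement.
* `tau = Inf` disables self-propulsion (used by momentum-conservation
  checks); `xi = 0` short-circuits all noise draws.
* Pair distance exactly `R`: no interaction (the cutoff is a strict
  inequality).
* `transition_time()` works on the recorded cadence without interpolation;
  its dwell defaults to one recording interval, and a crossing must hold
  through the dwell window to count.
* `t_d` and recording intervals must be exact multiples of `dt`; violations
  are construction-time errors, not silent rounding.

## Reproducibility

Every stochastic entry point takes a seed; a run is fully determined by
(parameters, initial state, seed). With `xi = 0` runs are deterministic
outright, and the delay machinery at `t_d = 0` is bitwise identical to the
plain integrator. Trajectories and series can be written to multi-frame XYZ
and flat CSV with a JSON parameter sidecar, and read back to resume or
re-analyse.
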