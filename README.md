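# flock3d

Agent-based simulator for a minimal continuous model of three-dimensional
collective motion (flocking), for researchers in collective animal behaviour
and active matter who want a small, fully tested reference implementation of
speed-controlled swarming with noise and delayed interactions.

## The model

`N` identical agents move in a cubic periodic box of side `L`. Agent `i`
obeys

```
m dv_i/dt = (m/τ) (v0 − |v_i|) v_i/|v_i|  +  Σ_{j≠i} (c/r_ij²) r̂_ij  +  ξ_i(t)
```

- **speed control**: each agent relaxes its speed toward the preferred
  `v0` with time constant `τ`, along its own heading — there is no explicit
  alignment term;
- **radial repulsion**: inverse-square central force `c/r²` between pairs
  closer than the cutoff `R` (minimum-image distances, strict cutoff);
- **effective attraction**: the periodic boundaries keep the group
  together;
- **noise**: a random force of constant magnitude `ξ`, direction re-drawn
  uniformly per agent and update (velocity impulse `ξ·Δt/m` per step);
- **delay**: all deterministic forces can be evaluated `t_d = k·Δt` before
  the current time (ring-buffered force history).

These three deterministic ingredients alone produce stable spatial ordering,
measured by the efficiency `E(t) = |Σ v_i| / (N v0)` (1 = perfect alignment,
~N^(-1/2) = disorder), with ensemble structure summarized by histograms over
ratio-spaced times and the Binder cumulant
`B(E) = 1 − ⟨E⁴⟩/(3⟨E²⟩²)`.

The equations of motion are integrated with the explicit midpoint method
(`Δt = 10⁻³ s` reference), with cell-list neighbour search; the symmetric
two-agent scattering experiment uses forward Euler with explicit
step-size-error control.

## Worked example

```r
library(flock3d)

p <- desk_params()          # N = 50 at the reference density, L = 31.498 m
p
#> flock3d model parameters
#>   N = 50 agents, box L = 31.498 m (periodic), density N/L^3 = 0.0016 m^-3
#>   v0 = 5 m/s, tau = 1 s, m = 1 kg, c = 1 N m^2, R = 10 m
#>   xi = 0 N (linear scaling), dt = 0.001 s, t_d = 0 s (0 steps)

s0 <- init_disordered(p, seed = 1)
efficiency(s0, p)           # disordered start: E ~ N^(-1/2)
#> [1] 0.07070351

r <- run_sim(s0, p, T = 1e5, record_every = 200, seed = 1)
r
#> flock_run: 501 recorded frames, t in [0, 1e+05] s; final E = 0.9636
transition_time(r$series, threshold = 0.8)
#> [1] 36800
```

The run starts at `E ≈ 0.07` (50 random headings), stays disordered for
tens of thousands of seconds, then transitions abruptly and holds `E` near
1: at this desk scale the jump to sustained `E > 0.8` lands at
`t ≈ 3.7 × 10⁴ s` for this seed (seeds 1-5 complete between 2 and
6 × 10⁴ s). The two-agent alignment threshold behind this ordering:

```r
threshold_angle(d = 2, dt = 1e-4)   # deg; pairs align above, anti-align below
#> [1] 42.96875
```

Experiment drivers (`order_transition()`, `noise_hysteresis()`,
`delay_sweep()`) run seed-managed ensembles of these protocols; a thin
command-line wrapper with subcommands `order`, `noise`, `delay`, `pair`
is installed at `inst/cli/flock3d.R`.

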