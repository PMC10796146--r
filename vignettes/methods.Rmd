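---
title: "neurodyn: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neurodyn: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodyn)
```

This vignette is the package's account of its science: what the models and
algorithms are, which knobs matter, what the numerics do in corner cases,
and where the design was genuinely open.

## The composition model

A `dyn_node` owns named parameters, named numeric state vectors (shapes
frozen at creation), an update rule, and an ordered map of children. The
composition graph is a tree; the full state of a composite is the disjoint
union of its own states and its descendants', addressed by dotted paths
(`"INa.m"` is gate *m* of the sodium-channel child `INa`). Three rules make
records reproducible:

* **Update order.** Within a step, children update before the parent, in
  insertion order. An ion channel therefore advances its gates against the
  membrane potential of the *previous* substep and publishes a fresh
  conductance; the soma then integrates against those fresh conductances.
  In spiking networks the population node updates first (producing this
  step's spikes) and the synaptic pathways consume those same-step spikes —
  a single-step causal pipeline. Where the ordering between synaptic-current
  computation and neuronal integration was not externally fixed, this
  pipeline is the package's own convention, chosen because any fixed,
  documented order makes runs replayable; it is asserted by the
  composition-transparency test (a composite run equals a manual interleave
  of its children).
* **Seeding.** `run_simulation()` seeds R's RNG once at entry; identical
  `(model, inputs, seed)` give bit-identical records, and `reset_node()`
  restores the creation-time snapshot so run → reset → run is exact.
* **Divergence policy.** After every step each state vector is checked for
  finiteness; the first violation aborts with the step index and variable
  name rather than letting NaNs propagate. This costs a few percent of
  runtime at the package's problem sizes and pays for itself in debugging.

Delays are ring buffers rounded to the nearest integer step — no
interpolation, so a delayed read is exactly a stored value and tests can
compare against direct indexing. Monitors share one sampling stride per run
(`record_every`), which keeps the record rectangular: every series has the
same leading length as the time grid.

## Integrators

Explicit Runge–Kutta methods are driven entirely by Butcher tableaus
(`A`, `b`, `c`, order, optionally embedded `b̂`); registering the textbook
RK4 tableau reproduces the built-in `rk4` bit-for-bit because both run the
same stage loop. Tableau validation enforces `Σb = 1` (to 1e-12),
`c_i = Σ_j A_ij`, and strict lower-triangularity.

Exponential Euler integrates `dy/dt = a·y + r(t, y)` as
`y e^{a·dt} + (e^{a·dt} − 1)/a · r`, exact for the linear part. The factor
`(e^{a·dt} − 1)/a` is evaluated with `expm1`, switching to the Taylor form
`dt(1 + a·dt/2)` below `|a·dt| < 1e-8`; this is a numerical-stability choice
the mathematics leaves open, and it makes `a → 0` degrade smoothly to
forward Euler. Every conductance-based membrane and every synaptic kernel in
the zoo uses this scheme, because their equations are linear given frozen
conductances, so subthreshold dynamics are exact to machine precision at any
step size.

The adaptive stepper uses the Fehlberg 4(5) embedded pair with error
estimate `sqrt(mean(((y5 − y4)/(atol + rtol·|y|))²))`, acceptance at ≤ 1,
safety factor 0.9, growth clamped to [0.2, 5.0], and step clipped to
`[dt_min, dt_max]` — standard controller constants, stated here because no
external source fixes them. `dt_min = dt_max` reduces to fixed-step RKF45's
fifth-order member, which the tests exploit.

SDE steppers (Euler–Maruyama, Milstein with the `½ g ∂g (ΔW² − dt)`
correction for scalar noise, Stratonovich–Heun predictor–corrector) take
noise increments from the caller, never drawing internally. That decision
buys pathwise reproducibility, common-noise Itô-vs-Stratonovich comparisons,
and exact Brownian refinement in the strong-convergence tests. Milstein
refuses multi-dimensional noise (the non-commutative correction needs Lévy
areas, out of scope), and SDE stepping is fixed-step only.

## Sparse and event-driven operators

Connectivity is CSR with rows = presynaptic neurons and 0-based indices
(the package-wide id convention, also used in exported CSVs). The synaptic
direction is the transpose product: `out[j] = Σ_{active i} w(i→j)`, and the
event-driven operator iterates only over rows whose neuron spiked, using a
`sequence()`/`rowsum()` gather–scatter that accumulates in float64
regardless of input precision. Its oracle — the same product with events
cast to 0/1 floats — agrees to < 1e-10 on hundreds of random instances, and
a wall-clock test checks the qualitative scaling claim: event cost tracks
the number of active events, not the matrix size.

Matrix-free "JIT connectivity" regenerates each presynaptic row from a
counter-based stream at every call. The stream is fixed bit-exactly so any
implementation can materialize the identical matrix: row *r* of a spec with
seed *s* uses the Lehmer recurrence `x ← 16807·x mod (2³¹ − 1)` seeded by
`((s·69069 + r·1013904223) mod (2³¹ − 2)) + 1`, draws columns by geometric
skip sampling (`j ← j + 1 + ⌊log(1−u)/log(1−p)⌋`), and, for normal weights,
one further uniform per edge through `qnorm`. Every product stays below
2⁵³, so the recurrence is exact in doubles — the property the bit-equality
tests rest on. The fixed-probability connector materializes the same
stream, so a stored matrix and the matrix-free operator agree exactly for
equal seeds.

## The model zoo

**LIF** (`τ` ms, `V_rest`, `V_reset`, `V_th` mV, resistance `R`, refractory
`t_ref` ms): exponential-Euler subthreshold integration; spike at
`V ≥ V_th` after the substep, without threshold interpolation (the
fixed-step simulator convention); the closed-form interspike interval
`T = t_ref + τ·log((V_rest + RI − V_reset)/(V_rest + RI − V_th))` is the
test oracle, matched within 1% at dt = 0.01 ms.

**Hodgkin–Huxley**: squid-axon kinetics in the −65 mV convention
(C = 1 µF/cm², gNa = 120, gK = 36, gL = 0.3 mS/cm², ENa = 50, EK = −77,
EL = −54.387 mV), gates by exponential Euler on
`dx/dt = α(V)(1−x) − β(V)x` (clamped to [0,1]; the rational singularities in
α use a series expansion near their removable poles). Channels are child
nodes so the same composition machinery that builds networks builds neurons.

**Synapses**: all kernels advance by exact exponential decay with
event-driven increments; the dual-exponential difference-of-exponentials is
normalized so a unit event peaks at `g_max` at
`t_p = τ_r τ_d/(τ_d − τ_r)·log(τ_d/τ_r)`. Sign convention, used everywhere:
positive conductance, current `I = g(E_rev − V)` added to the membrane
equation. NMDA multiplies the magnesium block
`1/(1 + [Mg]/3.57·e^{−0.062V})`.

**COBA** (default 320 excitatory / 80 inhibitory LIF, p = 0.02): normalized
membrane `τ_m dV/dt = (E_L − V) + g_e(E_e − V) + g_i(E_i − V) + I_ext` with
conductances in leak units, τ_m = 20 ms, τ_e = 5 ms, τ_i = 10 ms, E_e = 0,
E_i = −80 mV, threshold −50 mV, reset −60 mV, 5 ms refractory — the
classical E/I benchmark constants — plus a constant suprathreshold drive
(default 12 mV equivalent) so the 400-neuron instance fires without
needing the full-size network's recurrent mass. Synaptic weights default to
*dyadic rationals* (0.5 and 4.0 leak units): sums of exactly representable
weights are association-independent, so the event-driven and dense-masked
pathways produce bit-identical rasters — turning the dense path into an
exact oracle rather than an approximate one.

**CANN** (ring of n neurons, length 2π): `τ du/dt = −u + W r(u) + I_ext`,
Gaussian kernel `J(d) = J0/(√(2π)a)·e^{−d²/2a²}` on the circular distance,
divisive normalization `r = u₊²/(1 + k Σ u₊²)` (with ρΔx = 1 absorbed), and
defaults τ = 1 ms, k = 8.1, a = 0.5, J0 = 4 from the classical
ring-attractor formulation. Translation invariance of the kernel makes bump
positions a line attractor: the slow-point finder recovers a family of bump
fixed points whose Jacobians each carry one near-zero eigenvalue (the
translation mode). A consequence worth stating plainly: because the rate
nonlinearity is quadratic at the origin, the Jacobian at `u = 0` is exactly
`−I/τ`, so the quiescent state is *linearly stable* at any recurrent gain —
the unstable objects on the energy landscape are the small-amplitude saddle
bumps between quiescence and the bump family, which the finder locates when
seeded at low amplitude.

**Rate models**: FitzHugh–Nagumo (`dv = v − v³/3 − w + I`,
`dw = (v + a − bw)/τ`), Wilson–Cowan with logistic response (classical
oscillatory constants), and the reduced two-variable decision model with
`H(x) = (ax − b)/(1 − e^{−d(ax−b)})` and
`ds/dt = −s/τ_s + (1 − s)γH`, using the standard mean-field
parameterization (a = 270, b = 108, d = 0.154, γ = 0.641, τ_s = 0.1 s).

## Training

The evaluated task is one-step-ahead, teacher-forced prediction of the
3-variable Lorenz series — deterministic and fair across methods; a
free-running generative mode exists but is not scored. The series is
standardized per variable with statistics from the training split only, and
mean squared error is reported on that standardized scale; without a fixed
convention a printed MSE would be meaningless across implementations. The
default split: 60 time units at dt = 0.01, first 10% of step pairs
discarded as washout, 70/30 train/test on the rest, all recorded in the
fit's metadata.

The reservoir's recurrent matrix is sparse normal rescaled to the target
spectral radius within 1e-6 (spectral radius < 1 underwrites the echo-state
property, which the tests verify as two-trajectory convergence under common
drive). The readout sees the states plus a constant bias column — the ridge
normal equations applied to an augmented design, not a different estimator.
Ridge solves via Cholesky on `XᵀX + λI`, falling back to an SVD least-norm
solution with a warning when λ = 0 meets a rank-deficient design. The RLS
downdate is formed as the symmetric outer product
`P − (Px)(Px)ᵀ/(1 + xᵀPx)`, which floating point keeps exactly symmetric —
the positive-definiteness invariant then holds without periodic
re-symmetrization. One RLS pass over a batch solves ridge with λ = α
exactly; pass *p* solves λ = α/p, a sharper identity than "approaches the
ridge solution" and the one the tests assert.

## Analysis

Phase planes: nullclines by sign-change scanning along grid lines with
`uniroot` polishing; fixed-point candidates from grid cells where both
components change sign, plus a coarse lattice of extra starts; damped
Newton with finite-difference Jacobians polishes to `‖F‖∞ ≤ 1e-10`;
duplicates merge within 1e-6 of the box span. Bifurcation scans rerun that
machinery per parameter-grid point and link branches across neighboring
parameters by nearest state distance, reporting stability changes at grid
resolution — brackets shrink proportionally under grid refinement, which is
tested at two resolutions. Scans are grid-based by design; arclength
continuation is out of scope.

Slow points minimize `q(x) = ½‖F(x)‖²`. The default optimizer is
Levenberg–Marquardt nonlinear least squares (`minpack.lm`), with plain
gradient descent plus backtracking available as `optimizer = "gd"`. LM is
the default because minimizing a sum of squares with a rank-deficient
Jacobian — exactly the situation on a line attractor — is LM's home ground,
and its damping handles the singular translation direction gracefully;
gradient descent needs orders of magnitude more iterations near the
attractor. Acceptance requires `‖F‖∞ ≤ tol` (default 1e-6); merging uses a
dedupe radius of `0.01·√dim` state units (configurable — nothing external
fixes it); candidates are sorted by `q` before merging so results are
invariant to seed ordering. Stability labels use a ±1e-3 margin on
`Re(λ)`: anything inside is reported `"marginal"`, which is what makes line
attractors come out honestly instead of as noise-sign "stable"/"unstable"
flips. For discrete maps, pass `F(x) = x_{t+1} − x_t` and read fixed points
of the map; this is noted per analysis because eigenvalue conventions
differ between flows and maps. Seeding is left to the caller with both
modes supported — trajectory-derived seeds (`cann_slow_point_seeds()`
simulates a bump, lets it settle, and rotates it around the ring) find the
attractor family; random or scaled-down seeds expose the saddles.

## The synthetic-data generators

`lorenz_series()` (σ = 10, ρ = 28, β = 8/3 — the chaotic regime) is
integrated with the package's own rk4 at dt ≤ 0.02, deliberately
dogfooding the numerical stack; determinism and attractor bounds are
tested, and for ρ < 1 the trajectory must decay to the origin, which pins
the generator's correctness independently of the chaotic regime.
`random_csr()` and `random_linear_system()` provide reproducible operator
and analyzer instances (the latter rescaled to a declared spectral radius).

What these fixtures emulate is the *mathematical* structure the algorithms
consume: chaotic but bounded task series, sparse Bernoulli connectivity,
linear systems with known equilibria. What they do not emulate is anything
measured: no recording noise, no non-stationarity, no heavy-tailed degree
distributions, no dale's-law sign structure beyond the E/I split. Passing
tests therefore certify the algorithms against their defining equations and
closed-form oracles, not against biological data.

## Problem sizes and runtime posture

The shipped tests and the acceptance script use: COBA at 400 neurons and
0.2–1 s of simulated time; CANN at 128 units with 25 slow-point seeds;
reservoirs of 80–400 units on 20–60 time units of Lorenz data with five
seeds per method; 200-instance operator batteries; 200-path strong
convergence at five step levels. These sizes were chosen so every
closed-form comparison is already at its asymptotic tolerance — enlarging
them changes runtimes, not verdicts — and they are recorded here as the
package's reference configuration.

## Known limitations

* No implicit solvers, so stiff multi-compartment-style problems are out of
  scope; no adaptive SDE stepping; no fractional equations.
* Delays are step-rounded; delay interpolation would be needed for
  convergence studies *in the delay*.
* The bifurcation scanner reports stability changes at grid resolution and
  does not follow folds; closely spaced branches can link incorrectly if
  the grid is coarser than their separation.
* Spiking models are analyzed via their subthreshold flows only; the reset
  discontinuity is outside the linearization machinery.
* The event-driven operators are single-threaded R; their scaling claim is
  about algorithmic cost in active events, not absolute throughput.
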