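# neurodyn

Composable brain-dynamics programming in R: build neural models from ion
channels up to spiking networks as trees of dynamical-system nodes, simulate
them reproducibly, train echo-state readouts, and analyze the resulting
dynamics automatically.

`neurodyn` is aimed at computational neuroscientists who want one stack for
the three things a modeling study needs:

1. **Simulation** — models at any level (channel → neuron → network) are
   `dyn_node` trees advanced by a fixed-step runner with seeded RNG, typed
   monitors, delay buffers, and a divergence guard. Spiking synaptic
   pathways run through *event-driven* compressed-sparse-row operators that
   touch only the rows of neurons that spiked, or through matrix-free
   "JIT connectivity" operators that regenerate random connectivity
   deterministically from a seed at every call instead of storing it.
2. **Training** — leaky-tanh echo-state reservoirs
   `x[t+1] = (1-a) x[t] + a tanh(W_rec x[t] + W_in u[t])` with linear
   readouts fit offline by ridge regression
   `W = (XᵀX + λI)⁻¹XᵀY` or online by FORCE / recursive least squares
   (`k = Px/(1+xᵀPx)`, `W ← W − k eᵀ`, `P ← P − (Px)(Px)ᵀ/(1+xᵀPx)`).
3. **Analysis** — 2D phase planes (nullclines, vector fields, fixed points
   with Jacobian eigenvalues), grid-based codimension-1/2 bifurcation scans,
   and high-dimensional slow-point search minimizing `q(x) = ½‖F(x)‖²`
   with finite-difference linearization — enough to expose, e.g., the line
   attractor of a ring continuous-attractor network (CANN).

The model zoo ships leaky integrate-and-fire and Hodgkin–Huxley neurons
(channels composable as child nodes), delta/exponential/dual-exponential/
alpha/NMDA synapse kernels, the COBA E/I benchmark network, a ring CANN with
divisive normalization, and the FitzHugh–Nagumo, Wilson–Cowan, and reduced
two-variable decision rate models. Numerics: explicit Runge–Kutta via
Butcher tableaus (user-extensible through `register_tableau()`), an embedded
Fehlberg 4(5) adaptive pair, exponential Euler (exact on linear equations),
and Euler–Maruyama / Milstein / Stratonovich–Heun SDE steppers on
caller-supplied noise.

## Worked example

Simulate the 400-neuron COBA network with event-driven synapses, then ask
the phase-plane analyzer about the decision model under a 30 Hz stimulus:

```r
library(neurodyn)

net <- build_coba(n_exc = 320, n_inh = 80, p = 0.02, seed = 1)
rec <- run_simulation(net, duration = 1000, dt = 0.1,
                      monitors = "spike", seed = 4)
rate <- firing_rate(rec$series$spike > 0, window = 50, dt = 0.1)
cat(sprintf("population rate: %.1f Hz (mean over 1 s)\n", mean(rate)))
#> population rate: 48.2 Hz (mean over 1 s)

phase_plane_2d(decision_vector_field(mu0 = 30, coherence = 0),
               c(0, 1), c(0, 1), n_grid = 40, tol = 1e-9)
#> <phase_plane> 3 fixed point(s)
#>   (0.0518072, 0.658694)  stable  max Re(lambda) = -6.162
#>   (0.424456, 0.424456)  unstable  max Re(lambda) = 4.347
#>   (0.658694, 0.0518072)  stable  max Re(lambda) = -6.162
```

The network settles into irregular asynchronous firing near 50 Hz; the
stimulated decision circuit is bistable — two mirror-image choice attractors
separated by an unstable symmetric saddle, read off from the sign of the
largest Jacobian eigenvalue at each fixed point.

Rebuilding the network with `pathway = "dense"` swaps the event-driven
operators for a dense masked matrix product and reproduces the identical
spike raster for equal seeds — the dense path is the oracle against which
the sparse operators are tested.

A command-line launcher for config-driven runs
(`simulate | train | analyze | fixtures | selftest`) ships in
`inst/cli/neurodyn`; configs are YAML or JSON, and every run directory
contains a `metadata.json` that re-executes the run byte-identically.

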