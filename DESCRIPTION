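Package: neurodyn
Title: Composable Neural Dynamics: Simulation, Training, and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A general-purpose toolkit for programming brain dynamics models
    in R. Provides hierarchically composable dynamical-system nodes (channel
    to neuron to network), fixed-step and adaptive Runge-Kutta, exponential
    Euler and stochastic (Euler-Maruyama, Milstein, Stratonovich-Heun)
    integrators, event-driven compressed-sparse-row and matrix-free
    just-in-time connectivity operators for spiking networks, a model zoo
    (leaky integrate-and-fire, Hodgkin-Huxley, conductance-based E/I
    networks, continuous attractor networks, rate models), offline (ridge)
    and online (FORCE/recursive least squares) training of echo-state
    reservoir readouts, and automatic dynamics analysis: phase planes,
    codimension-1/2 bifurcation scans, and high-dimensional slow-point
    finding with Jacobian linearization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
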