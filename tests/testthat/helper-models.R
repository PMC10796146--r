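# Shared fixtures, built in code.

# minimal counter node: state x increments by `step` each update
counter_node <- function(name = "c", step = 1, x0 = 0) {
  dyn_node(name, params = list(step = step), states = list(x = x0),
           update = function(node, t, dt, inp)
             node$states$x <- node$states$x + node$params$step)
}

# node whose update draws from the R RNG (for determinism checks)
noisy_node <- function(name = "noisy", n = 5L) {
  dyn_node(name, states = list(x = numeric(n)),
           update = function(node, t, dt, inp)
             node$states$x <- node$states$x + rnorm(length(node$states$x)))
}

# standard LIF test parameters matching lif_neuron() defaults used in tests
lif_test_params <- list(tau = 10, V_rest = 0, V_reset = 0, V_th = 15,
                        R = 1, t_ref = 2)

make_test_lif <- function() do.call(lif_neuron, lif_test_params)

# independent dense oracle for CSR products
dense_matvec_oracle <- function(m, v, transpose = FALSE) {
  d <- csr_to_dense(m)
  if (transpose) as.numeric(crossprod(d, v)) else as.numeric(d %*% v)
}

# mean ISI from a spike record of a single neuron
mean_isi <- function(rec) {
  st <- rec$times[rec$series$spike[, 1L] > 0]
  mean(diff(st))
}
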