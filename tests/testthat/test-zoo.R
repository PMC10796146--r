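test_that("LIF stays silent below threshold and matches the closed-form ISI above it", {
  lif <- make_test_lif()
  # R*I < V_th - V_rest: no spikes ever
  sub <- run_simulation(lif, 500, 0.1, inputs = list(I = 14),
                        monitors = "spike", seed = 1)
  expect_equal(sum(sub$series$spike), 0)
  # I = 0 from rest: V stays at V_rest
  rest <- run_simulation(lif, 100, 0.1, inputs = list(I = 0),
                         monitors = "V", seed = 1)
  expect_true(all(abs(rest$series$V) < 1e-12))
  # suprathreshold: simulated ISI within 1% of the closed form
  rec <- run_simulation(lif, 300, 0.01, inputs = list(I = 30),
                        monitors = "spike", seed = 1)
  expect_lt(abs(mean_isi(rec) - lif_isi(lif_test_params, 30)) /
              lif_isi(lif_test_params, 30), 0.01)
})

test_that("HH neuron rests at gate steady states and spikes reproducibly", {
  hh <- hh_neuron()
  rec <- run_simulation(hh, 80, 0.01,
                        monitors = c("V", "IK.n", "INa.m", "INa.h"),
                        seed = 1)
  V <- tail(rec$series$V[, 1], 1)
  an <- function(V) 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10))
  bn <- function(V) 0.125 * exp(-(V + 65) / 80)
  am <- function(V) 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10))
  bm <- function(V) 4 * exp(-(V + 65) / 18)
  ah <- function(V) 0.07 * exp(-(V + 65) / 20)
  bh <- function(V) 1 / (1 + exp(-(V + 35) / 10))
  expect_equal(tail(rec$series[["IK.n"]][, 1], 1),
               an(V) / (an(V) + bn(V)), tolerance = 1e-4)
  expect_equal(tail(rec$series[["INa.m"]][, 1], 1),
               am(V) / (am(V) + bm(V)), tolerance = 1e-4)
  expect_equal(tail(rec$series[["INa.h"]][, 1], 1),
               ah(V) / (ah(V) + bh(V)), tolerance = 1e-4)
  # strong step current: positive, repeatable spike count
  r1 <- run_simulation(hh, 300, 0.01, inputs = list(I = 10),
                       monitors = "spike", seed = 2)
  r2 <- run_simulation(hh, 300, 0.01, inputs = list(I = 10),
                       monitors = "spike", seed = 2)
  expect_gt(sum(r1$series$spike), 0)
  expect_identical(r1$series$spike, r2$series$spike)
})

test_that("gate kinetics tend to 0.5 under symmetric rates and stay in [0, 1]", {
  x <- 0.9
  for (k in 1:2000) x <- neurodyn:::gate_step(x, 0.2, 0.2, 0.1)
  expect_equal(x, 0.5, tolerance = 1e-10)
  # fuzz: gates remain in range under strong random input
  hh <- hh_neuron()
  set.seed(4)
  reset_node(hh)
  ok <- TRUE
  for (k in 1:20000) {
    step_node(hh, k * 0.01, 0.01, list(I = runif(1, -30, 60)))
    g <- c(hh$children$IK$states$n, hh$children$INa$states$m,
           hh$children$INa$states$h)
    if (any(g < 0) || any(g > 1) || !is.finite(hh$states$V)) {
      ok <- FALSE
      break
    }
  }
  expect_true(ok)
})

test_that("synapse kernels follow their closed-form impulse responses", {
  dt <- 0.01
  # no events: current decays to zero
  s <- synapse_state("expon", g_max = 1, tau = 5, mode = "current")
  s$g <- 2
  for (k in 1:3000) I <- synapse_step(s, FALSE, dt = dt)
  expect_lt(abs(I), 1e-2)
  # single event, single-exponential: g(t) = g_max exp(-t/tau)
  s <- synapse_state("expon", g_max = 0.7, tau = 5, mode = "current")
  trace <- numeric(500)
  for (k in 1:500)
    trace[k] <- synapse_step(s, k == 1, dt = dt)
  ts <- (0:499) * dt
  expect_lt(max(abs(trace - 0.7 * exp(-ts / 5))), 1e-10)
  # dual-exponential: simulated argmax within one dt of the analytic peak
  s <- synapse_state("dual_expon", g_max = 1, tau_r = 0.8, tau_d = 6,
                     mode = "current")
  trace <- numeric(3000)
  for (k in 1:3000) trace[k] <- synapse_step(s, k == 1, dt = dt)
  t_peak <- (which.max(trace) - 1) * dt
  expect_lt(abs(t_peak - dual_expon_peak_time(0.8, 6)), dt + 1e-12)
  expect_equal(max(trace), 1, tolerance = 1e-6)  # normalized peak = g_max
  # alpha kernel peaks at t = tau with value g_max
  s <- synapse_state("alpha", g_max = 2, tau = 3, mode = "current")
  trace <- numeric(2000)
  for (k in 1:2000) trace[k] <- synapse_step(s, k == 1, dt = dt)
  expect_lt(abs((which.max(trace) - 1) * dt - 3), dt + 1e-12)
  expect_equal(max(trace), 2, tolerance = 1e-4)
  # NMDA magnesium block attenuates at hyperpolarized potentials
  sn <- function(V) {
    s <- synapse_state("nmda", g_max = 1, tau_r = 2, tau_d = 100,
                       mode = "current")
    synapse_step(s, TRUE, V_post = V, dt = dt)
    synapse_step(s, FALSE, V_post = V, dt = dt)  # one decay step past onset
  }
  expect_lt(sn(-70), sn(-20))
  expect_error(synapse_state("gaba_q"), "arg")
})

test_that("COBA fires irregular asynchronous activity and both pathways agree", {
  net <- build_coba(seed = 3)
  rec <- run_simulation(net, 1000, 0.1, monitors = "spike", seed = 4)
  rate <- 1000 * sum(rec$series$spike) / (400 * 1000)
  expect_gt(rate, 1)
  expect_lt(rate, 200)
  # irregular: coefficient of variation of population counts well above 0
  counts <- rowSums(rec$series$spike)
  expect_gt(sd(counts), 0)
  # p = 0 with subthreshold drive: silent
  silent <- build_coba(p = 0, seed = 3, I_ext = 5)
  rec0 <- run_simulation(silent, 300, 0.1, monitors = "spike", seed = 4)
  expect_equal(sum(rec0$series$spike), 0)
  # dense-masked and event-CSR pathways: identical rasters, same seed
  re <- run_simulation(build_coba(seed = 5), 200, 0.1,
                       monitors = "spike", seed = 6)
  rd <- run_simulation(build_coba(seed = 5, pathway = "dense"), 200, 0.1,
                       monitors = "spike", seed = 6)
  expect_identical(re$series$spike, rd$series$spike)
})

test_that("CANN holds a persistent bump where the stimulus was", {
  net <- cann_network(n = 128)
  dt <- 0.05
  # u = 0, no input: stays 0
  reset_node(net)
  for (k in 1:100) step_node(net, 0, dt, list(Iext = 0))
  expect_equal(net$states$u, numeric(128))
  # stimulate at 0.5, remove, bump persists at the stimulus center
  reset_node(net)
  stim <- cann_stimulus(net, center = 0.5)
  for (k in 1:400) step_node(net, 0, dt, list(Iext = stim))
  for (k in 1:400) step_node(net, 0, dt, list(Iext = 0))
  u1 <- net$states$u
  expect_gt(max(u1), 0.1)
  spacing <- 2 * pi / 128
  expect_lt(abs(cann_bump_center(net, u1) - 0.5), spacing)
  # drift under zero input < one lattice spacing per second
  for (k in 1:(1000 / dt)) step_node(net, 0, dt, list(Iext = 0))
  expect_lt(abs(cann_bump_center(net, net$states$u) - 0.5), 2 * spacing)
  # rotating the initial bump rotates the final bump identically
  shift <- 32L
  reset_node(net)
  net$states$u <- u1[((seq_len(128) - 1L - shift) %% 128L) + 1L]
  for (k in 1:200) step_node(net, 0, dt, list(Iext = 0))
  u_rot <- net$states$u
  reset_node(net)
  net$states$u <- u1
  for (k in 1:200) step_node(net, 0, dt, list(Iext = 0))
  u_ref <- net$states$u
  expect_equal(u_rot, u_ref[((seq_len(128) - 1L - shift) %% 128L) + 1L],
               tolerance = 1e-10)
})

test_that("rate-model derivatives match their analytic structure", {
  # FHN: exactly one real fixed point at default parameters, stable, v* < -1
  fp <- fhn_fixed_points()
  expect_length(fp, 1L)
  expect_lt(fp[[1]]$x[["v"]], -1)
  expect_true(all(Re(fp[[1]]$eigenvalues) < 0))
  expect_lt(max(abs(fhn_derivatives(fp[[1]]$x[["v"]], fp[[1]]$x[["w"]]))),
            1e-10)
  # decision model at zero stimulus is symmetric under (s1 <-> s2)
  d12 <- decision_derivatives(0.2, 0.6)
  d21 <- decision_derivatives(0.6, 0.2)
  expect_equal(d12, rev(d21), tolerance = 1e-14)
  # Wilson-Cowan with zero couplings relaxes to the sigmoid of its input
  S <- function(x, a, th) 1 / (1 + exp(-a * (x - th)))
  f <- wc_vector_field(w_ee = 0, w_ei = 0, w_ie = 0, w_ii = 0,
                       I_e = 5, I_i = 2)
  y <- c(0.1, 0.9)
  for (k in 1:4000) y <- y + 0.01 * f(y)
  # scalar fixed-point oracle: e* = S_e(I_e), i* = S_i(I_i)
  expect_equal(y, c(S(5, 1.3, 4), S(2, 2, 3.7)), tolerance = 1e-6)
})
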