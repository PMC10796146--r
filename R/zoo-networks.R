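# Network models: the E/I conductance-based benchmark (COBA) and the ring
# continuous-attractor network (CANN).

#' E/I balanced conductance-based network (COBA)
#'
#' LIF population (excitatory + inhibitory) with exponential
#' conductance-based synapses and fixed-probability random connectivity.
#' Normalized membrane equation (conductances in units of the leak):
#' `tau_m dV/dt = (E_L - V) + g_e (E_e - V) + g_i (E_i - V) + I_ext`,
#' integrated by exponential Euler with conductances frozen within the step.
#' Pipeline per step: membrane integration and spike detection first, then
#' conductance decay plus same-step synaptic increments, so synapses read
#' presynaptic spikes from the current step.
#'
#' Synaptic weights default to dyadic rationals (0.5, 4.0), which are exact
#' in binary floating point, so the `"event"` (event-driven CSR) and
#' `"dense"` (masked BLAS matrix product) pathways produce bit-identical
#' rasters for equal seeds.
#'
#' @param n_exc,n_inh population sizes (default 320/80).
#' @param p connection probability (each of the four E/I blocks uses the
#'   same p).
#' @param seed integer seed for the connectivity (and, offset by one, the
#'   initial-voltage jitter).
#' @param pathway `"event"` for event-driven CSR operators or `"dense"` for
#'   the dense masked oracle pathway.
#' @param we,wi excitatory/inhibitory weights (leak-conductance units).
#' @param tau_m,tau_e,tau_i membrane and synaptic time constants, ms.
#' @param E_L,E_e,E_i,V_th,V_reset potentials, mV.
#' @param t_ref refractory period, ms.
#' @param I_ext constant external drive, mV (suprathreshold for
#'   `E_L + I_ext > V_th`).
#' @param name node name.
#' @return a `dyn_node` with states `V`, `ge`, `gi`, `spike`, `refr`.
#' @export
build_coba <- function(n_exc = 320L, n_inh = 80L, p = 0.02, seed = 1L,
                       pathway = c("event", "dense"),
                       we = 0.5, wi = 4.0,
                       tau_m = 20, tau_e = 5, tau_i = 10,
                       E_L = -60, E_e = 0, E_i = -80,
                       V_th = -50, V_reset = -60, t_ref = 5,
                       I_ext = 12, name = "coba") {
  pathway <- match.arg(pathway)
  if (!(p > 0 && p <= 1) && p != 0)
    stop("parameter error: p must lie in [0, 1]", call. = FALSE)
  n <- n_exc + n_inh
  We <- fixed_prob_conn(n_exc, n, p, seed = seed * 1000 + 1, weight = we)
  Wi <- fixed_prob_conn(n_inh, n, p, seed = seed * 1000 + 2, weight = wi)
  We_d <- if (pathway == "dense") csr_to_dense(We) else NULL
  Wi_d <- if (pathway == "dense") csr_to_dense(Wi) else NULL
  # deterministic initial-voltage jitter, independent of the run seed
  u <- vapply(seq_len(n) - 1L, function(i) {
    s <- lehmer_seed(seed * 1000 + 3, i)
    lehmer_next(s) / LEHMER_M
  }, numeric(1))
  V0 <- V_reset + (V_th - V_reset) * u

  dyn_node(
    name,
    params = list(n_exc = n_exc, n_inh = n_inh, p = p, seed = seed,
                  pathway = pathway, we = we, wi = wi,
                  tau_m = tau_m, tau_e = tau_e, tau_i = tau_i,
                  E_L = E_L, E_e = E_e, E_i = E_i, V_th = V_th,
                  V_reset = V_reset, t_ref = t_ref, I_ext = I_ext,
                  We = We, Wi = Wi, We_d = We_d, Wi_d = Wi_d),
    states = list(V = V0, ge = numeric(n), gi = numeric(n),
                  spike = numeric(n), refr = numeric(n)),
    update = function(node, t, dt, inp) {
      p <- node$params
      st <- node$states
      I <- inp$I
      if (is.null(I)) I <- p$I_ext
      V <- st$V
      ge <- st$ge
      gi <- st$gi
      refr <- pmax(st$refr - dt, 0)
      in_ref <- refr > 0
      # exponential Euler with frozen conductances:
      # dV/dt = a V + r, a = -(1+ge+gi)/tau_m,
      # r = (E_L + ge E_e + gi E_i + I)/tau_m
      a <- -(1 + ge + gi) / p$tau_m
      r <- (p$E_L + ge * p$E_e + gi * p$E_i + I) / p$tau_m
      ead <- exp(a * dt)
      Vn <- V * ead + expm1(a * dt) / a * r
      Vn[in_ref] <- p$V_reset
      spk <- (Vn >= p$V_th) & !in_ref
      Vn[spk] <- p$V_reset
      refr[spk] <- p$t_ref
      # same-step spikes drive the synaptic pathways
      spk_e <- spk[seq_len(p$n_exc)]
      spk_i <- spk[p$n_exc + seq_len(p$n_inh)]
      ge <- ge * exp(-dt / p$tau_e)
      gi <- gi * exp(-dt / p$tau_i)
      if (p$pathway == "event") {
        if (any(spk_e)) ge <- ge + event_csr_matvec(p$We, spk_e, TRUE)
        if (any(spk_i)) gi <- gi + event_csr_matvec(p$Wi, spk_i, TRUE)
      } else {
        ge <- ge + as.vector(crossprod(p$We_d, as.numeric(spk_e)))
        gi <- gi + as.vector(crossprod(p$Wi_d, as.numeric(spk_i)))
      }
      node$states$V <- Vn
      node$states$ge <- ge
      node$states$gi <- gi
      node$states$spike <- as.numeric(spk)
      node$states$refr <- refr
    })
}

# ---- continuous attractor network -----------------------------------------

#' Ring continuous-attractor neural network (CANN)
#'
#' `tau du/dt = -u + W r(u) + I_ext` on a ring of `n` neurons with the
#' translation-invariant Gaussian kernel of [ring_gaussian_weights()] and
#' divisive normalization
#' `r = u_+^2 / (1 + k * rho * sum(u_+^2) * dx)`, `u_+ = max(u, 0)`,
#' where `rho = n/L` and `dx = L/n` (so `rho * dx = 1`). Default constants
#' follow the classical ring-attractor formulation (`tau = 1`, `k = 8.1`,
#' `a = 0.5`, `J0 = 4`, `L = 2*pi`).
#'
#' @param n neurons on the ring.
#' @param tau time constant, ms.
#' @param k global-inhibition (divisive normalization) strength.
#' @param a kernel width.
#' @param J0 kernel peak scale.
#' @param L ring length.
#' @param name node name.
#' @return a `dyn_node` with states `u` and `r`; the kernel matrix and
#'   positions are in `params`.
#' @export
cann_network <- function(n = 128L, tau = 1, k = 8.1, a = 0.5, J0 = 4,
                         L = 2 * pi, name = "cann") {
  W <- ring_gaussian_weights(n, J0, a, L)
  x <- ring_positions(n, L)
  dyn_node(
    name,
    params = list(n = n, tau = tau, k = k, a = a, J0 = J0, L = L,
                  W = W, x = x),
    states = list(u = numeric(n), r = numeric(n)),
    update = function(node, t, dt, inp) {
      p <- node$params
      Iext <- inp$Iext
      if (is.null(Iext)) Iext <- 0
      u <- node$states$u
      r <- cann_rate(u, p$k)
      drive <- as.vector(p$W %*% r) + Iext
      # exponential Euler: du/dt = -u/tau + drive/tau
      un <- drive + (u - drive) * exp(-dt / p$tau)
      node$states$u <- un
      node$states$r <- cann_rate(un, p$k)
    })
}

#' Divisively normalized CANN firing rate
#' @param u synaptic-input state vector.
#' @param k normalization strength (with `rho*dx = 1` absorbed).
#' @export
cann_rate <- function(u, k) {
  up2 <- pmax(u, 0)^2
  up2 / (1 + k * sum(up2))
}

#' Time derivative of the CANN state (for analyzers/integrators)
#' @param net a [cann_network()] node.
#' @param u state vector.
#' @param Iext external input vector (default 0).
#' @return `du/dt`.
#' @export
cann_derivatives <- function(net, u, Iext = 0) {
  p <- net$params
  (-u + as.vector(p$W %*% cann_rate(u, p$k)) + Iext) / p$tau
}

#' Gaussian bump stimulus on the ring
#' @param net a [cann_network()] node.
#' @param center bump center position.
#' @param A amplitude (default 10).
#' @return input vector `A * exp(-d(x, center)^2 / (4 a^2))`.
#' @export
cann_stimulus <- function(net, center = 0, A = 10) {
  p <- net$params
  d <- abs(p$x - center)
  d <- pmin(d, p$L - d)
  A * exp(-d^2 / (4 * p$a^2))
}

#' Circular center of mass of a bump state
#' @param net a [cann_network()] node.
#' @param u state vector (nonnegative part used as weights).
#' @return position on the ring (same units as `ring_positions()`).
#' @export
cann_bump_center <- function(net, u) {
  p <- net$params
  w <- pmax(u, 0)
  th <- p$x * 2 * pi / p$L
  atan2(sum(w * sin(th)), sum(w * cos(th))) * p$L / (2 * pi)
}
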