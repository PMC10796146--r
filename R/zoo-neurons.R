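# Spiking neuron models. Sign conventions used throughout the zoo: positive
# conductances, every membrane current enters as I = g * (E_rev - V) added
# to the membrane equation; spike detection is V >= V_th after the
# integration substep, without threshold interpolation.

#' Leaky integrate-and-fire population
#'
#' Subthreshold dynamics `tau * dV/dt = -(V - V_rest) + R*I`, integrated by
#' exponential Euler (exact for constant input within a step). On `V >= V_th`
#' the neuron emits a spike, `V` is clamped to `V_reset`, and integration is
#' suspended for `t_ref` ms. For constant suprathreshold input the
#' inter-spike interval has the closed form
#' `T = t_ref + tau * log((V_rest + R*I - V_reset)/(V_rest + R*I - V_th))`.
#'
#' @param n number of neurons.
#' @param tau membrane time constant, ms.
#' @param V_rest,V_reset,V_th resting, reset and threshold potentials, mV
#'   (`V_reset < V_th` required).
#' @param R input resistance (arbitrary consistent units).
#' @param t_ref absolute refractory period, ms.
#' @param V_init initial potential (scalar or length-n), default `V_rest`.
#' @param input name of the external input carrying the current (default
#'   `"I"`).
#' @param name node name.
#' @return a `dyn_node` with states `V`, `spike` (0/1), `refr` (remaining
#'   refractory time, ms).
#' @export
lif_neuron <- function(n = 1L, tau = 10, V_rest = 0, V_reset = 0, V_th = 10,
                       R = 1, t_ref = 0, V_init = V_rest, input = "I",
                       name = "lif") {
  if (!(V_reset < V_th)) stop("V_reset must be < V_th", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  dyn_node(
    name,
    params = list(tau = tau, V_rest = V_rest, V_reset = V_reset,
                  V_th = V_th, R = R, t_ref = t_ref, input = input),
    states = list(V = rep(as.numeric(V_init), length.out = n),
                  spike = numeric(n), refr = numeric(n)),
    update = function(node, t, dt, inp) {
      p <- node$params
      I <- inp[[p$input]]
      if (is.null(I)) I <- 0
      V <- node$states$V
      refr <- pmax(node$states$refr - dt, 0)
      in_ref <- refr > 0
      Vinf <- p$V_rest + p$R * I
      Vn <- Vinf + (V - Vinf) * exp(-dt / p$tau)
      Vn[in_ref] <- p$V_reset
      spk <- (Vn >= p$V_th) & !in_ref
      Vn[spk] <- p$V_reset
      refr[spk] <- p$t_ref
      node$states$V <- Vn
      node$states$spike <- as.numeric(spk)
      node$states$refr <- refr
    })
}

#' Closed-form LIF inter-spike interval under constant current
#' @param params named list with `tau`, `V_rest`, `V_reset`, `V_th`, `R`,
#'   `t_ref` (as in [lif_neuron()]).
#' @param I constant input current (must be suprathreshold).
#' @return interval in ms (`Inf` if subthreshold).
#' @export
lif_isi <- function(params, I) {
  p <- params
  Vinf <- p$V_rest + p$R * I
  if (Vinf <= p$V_th) return(Inf)
  p$t_ref + p$tau * log((Vinf - p$V_reset) / (Vinf - p$V_th))
}

# ---- Hodgkin-Huxley channels ----------------------------------------------

# x/(1 - exp(-x/y)) with its x -> 0 limit y, elementwise
vtrap <- function(x, y) {
  small <- abs(x / y) < 1e-6
  out <- x / (1 - exp(-x / y))
  out[small] <- y * (1 + x[small] / (2 * y))
  out
}

# advance a gate one step by exponential Euler on dx/dt = a(1-x) - b x
gate_step <- function(x, a, b, dt) {
  tot <- a + b
  xinf <- a / tot
  xn <- xinf + (x - xinf) * exp(-tot * dt)
  pmin(pmax(xn, 0), 1)
}

#' Gate steady state alpha/(alpha+beta)
#' @param a,b forward/backward rates at the clamped voltage.
#' @export
gate_steady_state <- function(a, b) a / (a + b)

#' Delayed-rectifier potassium channel (n^4 kinetics)
#'
#' Standard squid-axon kinetics in the modern -65 mV resting convention:
#' `alpha_n = 0.01*vtrap(V + 55, 10)`, `beta_n = 0.125*exp(-(V + 65)/80)`.
#' Composed under a [cond_neuron()] the channel reads the parent's membrane
#' potential, advances its gate by exponential Euler, and exposes its
#' instantaneous conductance `g = g_max * n^4` and current `I = g*(E_rev-V)`.
#'
#' @param g_max maximal conductance (mS/cm^2).
#' @param E_rev reversal potential, mV.
#' @param V_init voltage used to initialize the gate at steady state.
#' @return a `dyn_node` with states `n`, `g`, `I`.
#' @export
potassium_channel <- function(g_max = 36, E_rev = -77, V_init = -65) {
  an <- function(V) 0.01 * vtrap(V + 55, 10)
  bn <- function(V) 0.125 * exp(-(V + 65) / 80)
  n0 <- gate_steady_state(an(V_init), bn(V_init))
  dyn_node(
    "IK",
    params = list(g_max = g_max, E_rev = E_rev, alpha = an, beta = bn),
    states = list(n = n0, g = g_max * n0^4, I = 0),
    update = function(node, t, dt, inp) {
      V <- node$parent$states$V
      p <- node$params
      n <- gate_step(node$states$n, p$alpha(V), p$beta(V), dt)
      g <- p$g_max * n^4
      node$states$n <- n
      node$states$g <- g
      node$states$I <- g * (p$E_rev - V)
    })
}

#' Transient sodium channel (m^3 h kinetics)
#'
#' `alpha_m = 0.1*vtrap(V + 40, 10)`, `beta_m = 4*exp(-(V + 65)/18)`,
#' `alpha_h = 0.07*exp(-(V + 65)/20)`, `beta_h = 1/(1 + exp(-(V + 35)/10))`.
#'
#' @inheritParams potassium_channel
#' @return a `dyn_node` with states `m`, `h`, `g`, `I`.
#' @export
sodium_channel <- function(g_max = 120, E_rev = 50, V_init = -65) {
  am <- function(V) 0.1 * vtrap(V + 40, 10)
  bm <- function(V) 4 * exp(-(V + 65) / 18)
  ah <- function(V) 0.07 * exp(-(V + 65) / 20)
  bh <- function(V) 1 / (1 + exp(-(V + 35) / 10))
  m0 <- gate_steady_state(am(V_init), bm(V_init))
  h0 <- gate_steady_state(ah(V_init), bh(V_init))
  dyn_node(
    "INa",
    params = list(g_max = g_max, E_rev = E_rev,
                  alpha_m = am, beta_m = bm, alpha_h = ah, beta_h = bh),
    states = list(m = m0, h = h0, g = g_max * m0^3 * h0, I = 0),
    update = function(node, t, dt, inp) {
      V <- node$parent$states$V
      p <- node$params
      m <- gate_step(node$states$m, p$alpha_m(V), p$beta_m(V), dt)
      h <- gate_step(node$states$h, p$alpha_h(V), p$beta_h(V), dt)
      g <- p$g_max * m^3 * h
      node$states$m <- m
      node$states$h <- h
      node$states$g <- g
      node$states$I <- g * (p$E_rev - V)
    })
}

#' Ohmic leak channel
#' @inheritParams potassium_channel
#' @return a `dyn_node` with states `g` (constant) and `I`.
#' @export
leak_channel <- function(g_max = 0.3, E_rev = -54.387) {
  dyn_node(
    "IL",
    params = list(g_max = g_max, E_rev = E_rev),
    states = list(g = g_max, I = 0),
    update = function(node, t, dt, inp) {
      p <- node$params
      node$states$I <- p$g_max * (p$E_rev - node$parent$states$V)
    })
}

#' Conductance-based neuron composed from ion-channel children
#'
#' Membrane equation `C dV/dt = sum_channels g_i*(E_i - V) + I_ext`.
#' Channels update first (reading the parent's `V` of the previous step),
#' then the soma integrates `V` by exponential Euler treating the fresh
#' channel conductances as frozen within the step:
#' `dV/dt = -(sum g_i)/C * V + (sum g_i E_i + I_ext)/C`.
#'
#' @param channels named list of channel nodes (e.g.
#'   `list(IK = potassium_channel(), INa = sodium_channel(), IL =
#'   leak_channel())`).
#' @param C membrane capacitance (uF/cm^2).
#' @param V_init initial potential, mV.
#' @param V_th spike-detection threshold, mV (default 0 for HH-type spikes).
#' @param input name of the external current input (default `"I"`).
#' @param name node name.
#' @return a `dyn_node` with states `V`, `spike` and the channels composed
#'   as children (gate states appear as e.g. `"IK.n"`, `"INa.m"`,
#'   `"INa.h"`).
#' @export
cond_neuron <- function(channels, C = 1, V_init = -65, V_th = 0,
                        input = "I", name = "neuron") {
  node <- dyn_node(
    name,
    params = list(C = C, V_th = V_th, input = input),
    states = list(V = as.numeric(V_init), spike = 0),
    update = function(node, t, dt, inp) {
      p <- node$params
      I <- inp[[p$input]]
      if (is.null(I)) I <- 0
      gsum <- 0
      gE <- 0
      for (ch in node$children) {
        gsum <- gsum + ch$states$g
        gE <- gE + ch$states$g * ch$params$E_rev
      }
      V <- node$states$V
      a <- -gsum / p$C
      r <- (gE + I) / p$C
      Vn <- ode_step_exp_euler(a, function(t, y) r, V, t, dt)
      node$states$spike <- as.numeric(Vn >= p$V_th & V < p$V_th)
      node$states$V <- Vn
    })
  if (is.null(names(channels)) && length(channels))
    names(channels) <- vapply(channels, function(x) x$name, character(1))
  for (nm in names(channels)) compose(node, channels[[nm]], nm)
  node
}

#' Classical Hodgkin-Huxley neuron
#'
#' Convenience wrapper assembling [cond_neuron()] with the standard
#' potassium, sodium, and leak channels at squid-axon constants
#' (C = 1 uF/cm^2, gNa = 120, gK = 36, gL = 0.3 mS/cm^2, ENa = 50,
#' EK = -77, EL = -54.387 mV).
#'
#' @param V_init initial potential, mV.
#' @param name node name.
#' @return a `dyn_node`; states include `"V"`, `"IK.n"`, `"INa.m"`,
#'   `"INa.h"`.
#' @export
hh_neuron <- function(V_init = -65, name = "hh") {
  cond_neuron(
    list(INa = sodium_channel(V_init = V_init),
         IK = potassium_channel(V_init = V_init),
         IL = leak_channel()),
    C = 1, V_init = V_init, V_th = 0, name = name)
}
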