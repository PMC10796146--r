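# Synapse kernels. All kinetic states advance by exact exponential decay
# (exponential Euler on their linear ODEs); presynaptic events arrive as
# instantaneous increments. Output convention: conductance mode returns
# I = g * (E_rev - V_post); current mode returns I = g; NMDA additionally
# multiplies the magnesium-block factor
# B(V) = 1 / (1 + [Mg]/3.57 * exp(-0.062 V)).

#' Create a synapse kernel state
#'
#' @param kind one of `"delta"`, `"expon"`, `"dual_expon"`, `"alpha"`,
#'   `"nmda"`.
#' @param n number of postsynaptic targets.
#' @param g_max peak conductance increment per incoming spike.
#' @param tau decay time constant, ms (`"expon"`, `"alpha"`).
#' @param tau_r,tau_d rise and decay time constants, ms
#'   (`"dual_expon"`, `"nmda"`; `tau_r < tau_d`).
#' @param mode `"conductance"` or `"current"` output.
#' @param E_rev reversal potential, mV (conductance mode).
#' @param mg magnesium concentration, mM (NMDA block; default 1).
#' @return environment of class `"synapse_state"`.
#' @export
synapse_state <- function(kind = c("expon", "delta", "dual_expon", "alpha",
                                   "nmda"),
                          n = 1L, g_max = 1, tau = 5, tau_r = 0.5,
                          tau_d = 8, mode = c("conductance", "current"),
                          E_rev = 0, mg = 1) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (kind %in% c("dual_expon", "nmda") && !(tau_r < tau_d))
    stop("parameter error: tau_r must be < tau_d", call. = FALSE)
  s <- new.env(parent = emptyenv())
  s$kind <- kind
  s$n <- as.integer(n)
  s$g_max <- g_max
  s$tau <- tau
  s$tau_r <- tau_r
  s$tau_d <- tau_d
  s$mode <- mode
  s$E_rev <- E_rev
  s$mg <- mg
  s$g <- numeric(n)
  s$h <- numeric(n)   # auxiliary state (rise component / alpha feeder)
  class(s) <- "synapse_state"
  s
}

#' Advance a synapse kernel one step and return the postsynaptic current
#'
#' @param s a [synapse_state()].
#' @param events logical (or 0/1 numeric) vector of presynaptic events
#'   mapped onto the `n` targets, or a numeric vector of pre-summed weighted
#'   increments (use `weights = NULL` then).
#' @param V_post postsynaptic potentials (conductance/NMDA modes).
#' @param dt step, ms.
#' @param weights per-target increment scale; defaults to `g_max`.
#' @return numeric postsynaptic current vector of length `n`. The
#'   conductance trace is available as `s$g`.
#' @export
synapse_step <- function(s, events, V_post = 0, dt = 0.1, weights = NULL) {
  stopifnot(inherits(s, "synapse_state"))
  inc <- if (is.logical(events)) as.numeric(events) else as.numeric(events)
  if (!is.null(weights)) inc <- inc * weights
  else if (is.logical(events)) inc <- inc * s$g_max
  switch(s$kind,
    delta = {
      s$g <- inc
    },
    expon = {
      s$g <- s$g * exp(-dt / s$tau) + inc
    },
    alpha = {
      # dg/dt = (h - g)/tau, dh/dt = -h/tau  =>  exact step
      e <- exp(-dt / s$tau)
      s$g <- (s$g + s$h * dt / s$tau) * e
      s$h <- s$h * e + inc * exp(1)    # peak of (t/tau)e^(1-t/tau) is g_max
    },
    dual_expon = ,
    nmda = {
      # g(t) = difference of exponentials; normalized so the peak is g_max
      tr <- s$tau_r; td <- s$tau_d
      tp <- tr * td / (td - tr) * log(td / tr)
      norm <- 1 / (exp(-tp / td) - exp(-tp / tr))
      s$h <- s$h * exp(-dt / tr) + inc * norm
      s$g <- s$g * exp(-dt / td) + inc * norm
    })
  g_eff <- if (s$kind %in% c("dual_expon", "nmda")) s$g - s$h else s$g
  out <- switch(s$mode,
    conductance = g_eff * (s$E_rev - V_post),
    current = g_eff)
  if (s$kind == "nmda")
    out <- out / (1 + s$mg / 3.57 * exp(-0.062 * V_post))
  out
}

#' Closed-form peak time of the dual-exponential kernel
#' @param tau_r,tau_d rise/decay constants, ms.
#' @export
dual_expon_peak_time <- function(tau_r, tau_d)
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)

#' Synapse kernel as a composable node
#'
#' Wraps [synapse_state()] in a `dyn_node`. Presynaptic events are read from
#' the input named by `input`; the postsynaptic potential, when needed, from
#' the input named by `v_input` (default 0 mV clamp).
#'
#' @inheritParams synapse_state
#' @param input input name carrying the event/increment vector.
#' @param v_input input name carrying `V_post` (optional).
#' @param name node name.
#' @return a `dyn_node` with states `g` (effective conductance) and `I`.
#' @export
synapse_kernel <- function(kind = "expon", n = 1L, g_max = 1, tau = 5,
                           tau_r = 0.5, tau_d = 8, mode = "conductance",
                           E_rev = 0, mg = 1, input = "events",
                           v_input = "V_post", name = "syn") {
  st <- synapse_state(kind, n, g_max, tau, tau_r, tau_d, mode, E_rev, mg)
  dyn_node(
    name,
    params = list(input = input, v_input = v_input, kernel = st),
    states = list(g = numeric(n), I = numeric(n)),
    update = function(node, t, dt, inp) {
      p <- node$params
      ev <- inp[[p$input]]
      if (is.null(ev)) ev <- logical(p$kernel$n)
      V <- inp[[p$v_input]]
      if (is.null(V)) V <- 0
      I <- synapse_step(p$kernel, ev, V, dt)
      k <- p$kernel
      node$states$g <- if (k$kind %in% c("dual_expon", "nmda")) k$g - k$h else k$g
      node$states$I <- I
    },
    reset = function(node) {
      k <- node$params$kernel
      k$g <- numeric(k$n)
      k$h <- numeric(k$n)
      node$states$g <- numeric(k$n)
      node$states$I <- numeric(k$n)
    })
}
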