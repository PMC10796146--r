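# Low-dimensional rate models used by the analyzers: FitzHugh-Nagumo,
# Wilson-Cowan, and the reduced two-variable decision model.

#' FitzHugh-Nagumo right-hand side
#'
#' `dv/dt = v - v^3/3 - w + Iext`; `dw/dt = (v + a - b*w)/tau`.
#'
#' @param v,w state variables.
#' @param a,b,tau,Iext parameters (defaults 0.7, 0.8, 12.5, 0).
#' @return numeric `c(dv, dw)`.
#' @export
fhn_derivatives <- function(v, w, a = 0.7, b = 0.8, tau = 12.5, Iext = 0) {
  c(v - v^3 / 3 - w + Iext, (v + a - b * w) / tau)
}

#' Vector-field closure for the FitzHugh-Nagumo model
#' @inheritParams fhn_derivatives
#' @return `function(y)` mapping `c(v, w)` to `c(dv, dw)`.
#' @export
fhn_vector_field <- function(a = 0.7, b = 0.8, tau = 12.5, Iext = 0) {
  function(y) fhn_derivatives(y[1L], y[2L], a, b, tau, Iext)
}

#' Analytic FitzHugh-Nagumo fixed point and Jacobian
#'
#' The fixed point solves the cubic `v - v^3/3 - (v + a)/b + Iext = 0`
#' (substituting the w-nullcline `w = (v + a)/b`); roots are found by
#' bisection on sign-change brackets. The Jacobian at a fixed point is
#' `[[1 - v^2, -1], [1/tau, -b/tau]]`.
#'
#' @inheritParams fhn_derivatives
#' @return list of fixed points, each with `x = c(v, w)`, `jacobian`,
#'   `eigenvalues`.
#' @export
fhn_fixed_points <- function(a = 0.7, b = 0.8, tau = 12.5, Iext = 0) {
  g <- function(v) v - v^3 / 3 - (v + a) / b + Iext
  vs <- seq(-5, 5, by = 0.01)
  gv <- g(vs)
  roots <- numeric()
  for (i in seq_len(length(vs) - 1L)) {
    if (gv[i] == 0) roots <- c(roots, vs[i])
    else if (gv[i] * gv[i + 1L] < 0) {
      lo <- vs[i]; hi <- vs[i + 1L]
      for (it in 1:200) {
        mid <- (lo + hi) / 2
        if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  lapply(roots, function(v) {
    J <- rbind(c(1 - v^2, -1), c(1 / tau, -b / tau))
    list(x = c(v = v, w = (v + a) / b), jacobian = J,
         eigenvalues = eigen(J, only.values = TRUE)$values)
  })
}

#' Wilson-Cowan population rates
#'
#' `de/dt = (-e + S_e(w_ee*e - w_ei*i + I_e))/tau_e`,
#' `di/dt = (-i + S_i(w_ie*e - w_ii*i + I_i))/tau_i`, with the logistic
#' response `S(x) = 1/(1 + exp(-a(x - theta)))`. Defaults are the classical
#' oscillatory parameter set (w_ee 16, w_ei 12, w_ie 15, w_ii 3).
#'
#' @param e,i excitatory/inhibitory activities in `[0, 1]`.
#' @param w_ee,w_ei,w_ie,w_ii coupling weights.
#' @param a_e,theta_e,a_i,theta_i sigmoid gains and thresholds.
#' @param tau_e,tau_i time constants, ms.
#' @param I_e,I_i external drives.
#' @return numeric `c(de, di)`.
#' @export
wc_derivatives <- function(e, i, w_ee = 16, w_ei = 12, w_ie = 15, w_ii = 3,
                           a_e = 1.3, theta_e = 4, a_i = 2, theta_i = 3.7,
                           tau_e = 1, tau_i = 1, I_e = 0, I_i = 0) {
  S <- function(x, a, th) 1 / (1 + exp(-a * (x - th)))
  de <- (-e + S(w_ee * e - w_ei * i + I_e, a_e, theta_e)) / tau_e
  di <- (-i + S(w_ie * e - w_ii * i + I_i, a_i, theta_i)) / tau_i
  c(de, di)
}

#' Vector-field closure for the Wilson-Cowan model
#' @param ... parameters forwarded to [wc_derivatives()].
#' @return `function(y)` mapping `c(e, i)` to `c(de, di)`.
#' @export
wc_vector_field <- function(...) {
  function(y) wc_derivatives(y[1L], y[2L], ...)
}

#' Reduced two-variable decision model right-hand side
#'
#' Gating variables `s1, s2` in `[0, 1]` with the effective input-output
#' curve `H(x) = (a*x - b)/(1 - exp(-d*(a*x - b)))` (x in nA, H in Hz) and
#' `ds/dt = -s/tau_s + (1 - s)*gamma*H(x)`, time in seconds.
#' Inputs: `x1 = J11*s1 - J12*s2 + I0 + JA_ext*mu0*(1 + c/100)`,
#' `x2 = J22*s2 - J21*s1 + I0 + JA_ext*mu0*(1 - c/100)`. Defaults follow the
#' standard reduced mean-field parameterization (a 270, b 108, d 0.154,
#' gamma 0.641, tau_s 0.1 s, J11 = J22 = 0.2609, J12 = J21 = 0.0497,
#' I0 = 0.3255 nA).
#'
#' @param s1,s2 gating variables.
#' @param a,b,d input-output curve parameters.
#' @param gamma kinetic scale; `tau_s` gating time constant, s.
#' @param tau_s gating time constant, s.
#' @param J11,J22,J12,J21 self/cross couplings, nA.
#' @param I0 background input, nA.
#' @param JA_ext stimulus coupling, nA/Hz.
#' @param mu0 stimulus strength, Hz.
#' @param coherence stimulus coherence c', percent.
#' @return numeric `c(ds1, ds2)`.
#' @export
decision_derivatives <- function(s1, s2, a = 270, b = 108, d = 0.154,
                                 gamma = 0.641, tau_s = 0.1,
                                 J11 = 0.2609, J22 = 0.2609,
                                 J12 = 0.0497, J21 = 0.0497,
                                 I0 = 0.3255, JA_ext = 5.2e-4,
                                 mu0 = 0, coherence = 0) {
  H <- function(x) {
    y <- a * x - b
    small <- abs(d * y) < 1e-8
    out <- y / (1 - exp(-d * y))
    out[small] <- 1 / d * (1 + d * y[small] / 2)
    out
  }
  x1 <- J11 * s1 - J12 * s2 + I0 + JA_ext * mu0 * (1 + coherence / 100)
  x2 <- J22 * s2 - J21 * s1 + I0 + JA_ext * mu0 * (1 - coherence / 100)
  c(-s1 / tau_s + (1 - s1) * gamma * H(x1),
    -s2 / tau_s + (1 - s2) * gamma * H(x2))
}

#' Vector-field closure for the decision model
#' @param ... parameters forwarded to [decision_derivatives()].
#' @return `function(y)` mapping `c(s1, s2)` to `c(ds1, ds2)`.
#' @export
decision_vector_field <- function(...) {
  function(y) decision_derivatives(y[1L], y[2L], ...)
}

#' FitzHugh-Nagumo as a composable node (rk4-integrated)
#' @inheritParams fhn_derivatives
#' @param v0,w0 initial state.
#' @param name node name.
#' @return a `dyn_node` with states `v`, `w`; external input `"Iext"`
#'   overrides the parameter when supplied to the runner.
#' @export
fhn_neuron <- function(a = 0.7, b = 0.8, tau = 12.5, Iext = 0,
                       v0 = -1, w0 = -0.5, name = "fhn") {
  dyn_node(
    name,
    params = list(a = a, b = b, tau = tau, Iext = Iext),
    states = list(v = v0, w = w0),
    update = function(node, t, dt, inp) {
      p <- node$params
      Ie <- inp$Iext
      if (is.null(Ie)) Ie <- p$Iext
      y <- c(node$states$v, node$states$w)
      f <- function(tt, yy) fhn_derivatives(yy[1L], yy[2L], p$a, p$b,
                                            p$tau, Ie)
      yn <- ode_step(f, y, t, dt, "rk4")
      node$states$v <- yn[1L]
      node$states$w <- yn[2L]
    })
}
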