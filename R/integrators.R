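# Numerical steppers. Deterministic ODE schemes are expressed through
# explicit Butcher tableaus so that user-registered methods and the built-ins
# share one code path; SDE schemes take externally drawn noise increments so
# that pathwise comparisons (Ito vs Stratonovich, strong convergence) run on
# common noise.

#' Construct and validate an explicit Butcher tableau
#'
#' @param A stage coefficient matrix (strictly lower triangular).
#' @param b output weights (must sum to 1 within 1e-12).
#' @param c stage nodes (`c_i` must equal the i-th row sum of `A`).
#' @param order classical order of the scheme.
#' @param b_hat optional embedded weights for error estimation.
#' @param name optional method name.
#' @return object of class `"butcher_tableau"`.
#' @export
make_tableau <- function(A, b, c, order, b_hat = NULL, name = NULL) {
  A <- as.matrix(A)
  s <- length(b)
  stopifnot(nrow(A) == s, ncol(A) == s, length(c) == s)
  if (abs(sum(b) - 1) > 1e-12)
    stop("inconsistent tableau: sum(b) != 1", call. = FALSE)
  if (any(A[upper.tri(A, diag = TRUE)] != 0))
    stop("inconsistent tableau: A must be strictly lower triangular",
         call. = FALSE)
  if (any(abs(rowSums(A) - c) > 1e-12))
    stop("inconsistent tableau: c_i must equal row sums of A", call. = FALSE)
  if (!is.null(b_hat)) {
    stopifnot(length(b_hat) == s)
    if (abs(sum(b_hat) - 1) > 1e-12)
      stop("inconsistent tableau: sum(b_hat) != 1", call. = FALSE)
  }
  structure(list(A = A, b = as.numeric(b), c = as.numeric(c),
                 order = as.integer(order), b_hat = b_hat,
                 name = name %||% "custom"),
            class = "butcher_tableau")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tableau_registry <- new.env(parent = emptyenv())

#' Register a named Butcher tableau
#' @param name method name usable in [ode_step()].
#' @param tableau a `"butcher_tableau"`.
#' @export
register_tableau <- function(name, tableau) {
  stopifnot(inherits(tableau, "butcher_tableau"))
  assign(name, tableau, envir = tableau_registry)
  invisible(tableau)
}

#' Look up a registered tableau by name
#' @param name method name.
#' @export
get_tableau <- function(name) {
  if (!exists(name, envir = tableau_registry, inherits = FALSE))
    stop("unknown ODE method: '", name, "'", call. = FALSE)
  get(name, envir = tableau_registry, inherits = FALSE)
}

.init_builtin_tableaus <- function() {
  register_tableau("euler", make_tableau(
    matrix(0, 1, 1), b = 1, c = 0, order = 1, name = "euler"))
  register_tableau("midpoint", make_tableau(
    rbind(c(0, 0), c(0.5, 0)), b = c(0, 1), c = c(0, 0.5),
    order = 2, name = "midpoint"))
  register_tableau("heun", make_tableau(
    rbind(c(0, 0), c(1, 0)), b = c(0.5, 0.5), c = c(0, 1),
    order = 2, name = "heun"))
  register_tableau("rk3", make_tableau(
    rbind(c(0, 0, 0), c(0.5, 0, 0), c(-1, 2, 0)),
    b = c(1, 4, 1) / 6, c = c(0, 0.5, 1), order = 3, name = "rk3"))
  register_tableau("rk4", make_tableau(
    rbind(c(0, 0, 0, 0), c(0.5, 0, 0, 0), c(0, 0.5, 0, 0), c(0, 0, 1, 0)),
    b = c(1, 2, 2, 1) / 6, c = c(0, 0.5, 0.5, 1), order = 4, name = "rk4"))
  # Fehlberg 4(5) embedded pair for the adaptive stepper
  A <- matrix(0, 6, 6)
  A[2, 1] <- 1 / 4
  A[3, 1:2] <- c(3 / 32, 9 / 32)
  A[4, 1:3] <- c(1932 / 2197, -7200 / 2197, 7296 / 2197)
  A[5, 1:4] <- c(439 / 216, -8, 3680 / 513, -845 / 4104)
  A[6, 1:5] <- c(-8 / 27, 2, -3544 / 2565, 1859 / 4104, -11 / 40)
  register_tableau("rkf45", make_tableau(
    A,
    b = c(16 / 135, 0, 6656 / 12825, 28561 / 56430, -9 / 50, 2 / 55),
    b_hat = c(25 / 216, 0, 1408 / 2565, 2197 / 4104, -1 / 5, 0),
    c = c(0, 1 / 4, 3 / 8, 12 / 13, 1, 1 / 2),
    order = 5, name = "rkf45"))
}

#' One explicit Runge-Kutta step
#'
#' @param f right-hand side `function(t, y)` returning `dy/dt` (same shape
#'   as `y`, side-effect free).
#' @param y current state (numeric vector).
#' @param t current time.
#' @param dt step size.
#' @param method a method name (`"euler"`, `"midpoint"`, `"heun"`, `"rk3"`,
#'   `"rk4"`, `"rkf45"`, or any name registered with [register_tableau()]),
#'   or a `"butcher_tableau"` object.
#' @return the state after one step.
#' @export
ode_step <- function(f, y, t, dt, method = "rk4") {
  tb <- if (inherits(method, "butcher_tableau")) method else get_tableau(method)
  s <- length(tb$b)
  k <- vector("list", s)
  for (i in seq_len(s)) {
    yi <- y
    if (i > 1L) for (j in seq_len(i - 1L))
      if (tb$A[i, j] != 0) yi <- yi + dt * tb$A[i, j] * k[[j]]
    k[[i]] <- f(t + tb$c[i] * dt, yi)
  }
  out <- y
  for (i in seq_len(s)) if (tb$b[i] != 0) out <- out + dt * tb$b[i] * k[[i]]
  out
}

#' Exponential Euler step for dy/dt = a*y + r(t, y)
#'
#' Exact for the linear part: `y' = y*exp(a*dt) + (exp(a*dt)-1)/a * r(t, y)`.
#' The factor `(exp(a*dt)-1)/a` is evaluated with `expm1` and switches to its
#' Taylor form below `|a*dt| < 1e-8`, so `a -> 0` degrades gracefully to
#' forward Euler.
#'
#' @param a linear coefficient (scalar or vector matching `y`).
#' @param r residual `function(t, y)` (may be `NULL` for r = 0).
#' @param y,t,dt state, time, step.
#' @return the state after one step.
#' @export
ode_step_exp_euler <- function(a, r, y, t, dt) {
  ad <- a * dt
  phi <- ifelse(abs(ad) < 1e-8,
                dt * (1 + ad / 2),       # Taylor: dt*(1 + a dt/2 + ...)
                expm1(ad) / a)
  rv <- if (is.null(r)) 0 else r(t, y)
  y * exp(ad) + phi * rv
}

#' One adaptive Runge-Kutta step with an embedded error estimate
#'
#' Uses a tableau carrying embedded weights (default the Fehlberg 4(5) pair).
#' The error estimate is `sqrt(mean(((y_hi - y_lo)/(atol + rtol*|y|))^2))`;
#' the step is accepted when it is <= 1 and the next step size follows the
#' standard safety-factor power law (safety 0.9, growth clamped to
#' [0.2, 5.0]) clipped to `[dt_min, dt_max]`.
#'
#' @inheritParams ode_step
#' @param rtol,atol relative and absolute tolerances.
#' @param dt_min,dt_max step-size bounds.
#' @return list with `y` (new state if accepted, input state otherwise),
#'   `dt` (suggested next step), `accepted` (flag), `err` (estimate).
#' @export
ode_step_adaptive <- function(f, y, t, dt, method = "rkf45",
                              rtol = 1e-6, atol = 1e-9,
                              dt_min = 1e-12, dt_max = Inf) {
  tb <- if (inherits(method, "butcher_tableau")) method else get_tableau(method)
  if (is.null(tb$b_hat))
    stop("adaptive stepping needs an embedded pair (b_hat)", call. = FALSE)
  stopifnot(dt_min <= dt_max)
  if (dt < dt_min * (1 - 1e-12))
    stop("stiffness error: dt underflow below dt_min", call. = FALSE)
  s <- length(tb$b)
  k <- vector("list", s)
  for (i in seq_len(s)) {
    yi <- y
    if (i > 1L) for (j in seq_len(i - 1L))
      if (tb$A[i, j] != 0) yi <- yi + dt * tb$A[i, j] * k[[j]]
    k[[i]] <- f(t + tb$c[i] * dt, yi)
  }
  y_hi <- y; y_lo <- y
  for (i in seq_len(s)) {
    if (tb$b[i] != 0) y_hi <- y_hi + dt * tb$b[i] * k[[i]]
    if (tb$b_hat[i] != 0) y_lo <- y_lo + dt * tb$b_hat[i] * k[[i]]
  }
  sc <- atol + rtol * pmax(abs(y), abs(y_hi))
  err <- sqrt(mean(((y_hi - y_lo) / sc)^2))
  accepted <- err <= 1
  fac <- if (err == 0) 5 else 0.9 * err^(-1 / tb$order)
  fac <- min(5, max(0.2, fac))
  dt_new <- min(dt_max, max(dt_min, dt * fac))
  if (!accepted && dt <= dt_min * (1 + 1e-12))
    stop("stiffness error: step rejected at dt_min", call. = FALSE)
  list(y = if (accepted) y_hi else y, dt = dt_new,
       accepted = accepted, err = err)
}

#' Integrate an ODE over an interval with the adaptive stepper
#'
#' Convenience driver looping [ode_step_adaptive()] from `t0` to `t1`.
#'
#' @inheritParams ode_step_adaptive
#' @param t0,t1 interval endpoints.
#' @param dt0 initial step.
#' @return list with `t` and `y` at accepted points (matrices/vectors).
#' @export
ode_solve_adaptive <- function(f, y0, t0, t1, dt0, method = "rkf45",
                               rtol = 1e-6, atol = 1e-9,
                               dt_min = 1e-12, dt_max = Inf) {
  t <- t0; y <- y0; dt <- min(dt0, dt_max)
  ts <- t0; ys <- list(y0)
  while (t < t1 - 1e-14) {
    dt <- min(dt, t1 - t)
    st <- ode_step_adaptive(f, y, t, dt, method, rtol, atol, dt_min, dt_max)
    if (st$accepted) {
      t <- t + dt
      y <- st$y
      ts <- c(ts, t)
      ys[[length(ys) + 1L]] <- y
    }
    dt <- st$dt
  }
  list(t = ts, y = do.call(rbind, ys))
}

# ---- stochastic steppers ---------------------------------------------------

#' One fixed-step SDE step on externally supplied noise
#'
#' Supported schemes: `"euler_maruyama"` (Ito), `"milstein"` (Ito, scalar
#' noise; adds `0.5*g*dg/dy*(dW^2 - dt)`), `"heun_stratonovich"`
#' (predictor-corrector, Stratonovich). Noise increments are drawn by the
#' caller (variance `dt` per Wiener component) and passed in, which keeps
#' paths reproducible and lets Ito/Stratonovich schemes run on common noise.
#'
#' @param f drift `function(t, y)`.
#' @param g diffusion `function(t, y)`; for scalar noise returns the shape of
#'   `y`, for multi-dimensional noise a matrix with one column per Wiener
#'   component.
#' @param y,t,dt state, time, step.
#' @param dW noise increment(s): scalar/vector for scalar noise, or a vector
#'   of one increment per Wiener component for multi noise.
#' @param method scheme name.
#' @param dg optional analytic `function(t, y)` for `dg/dy` (Milstein);
#'   defaults to a central finite difference.
#' @param wiener `"scalar"` or `"multi"`.
#' @return the state after one step.
#' @export
sde_step <- function(f, g, y, t, dt, dW,
                     method = c("euler_maruyama", "milstein",
                                "heun_stratonovich"),
                     dg = NULL, wiener = c("scalar", "multi")) {
  method <- match.arg(method)
  wiener <- match.arg(wiener)
  if (wiener == "multi") {
    G <- g(t, y)                       # length(y) x n_wiener
    if (method == "milstein")
      stop("unsupported method: milstein with multi-dimensional noise",
           call. = FALSE)
    gdW <- as.numeric(G %*% dW)
    if (method == "euler_maruyama") return(y + f(t, y) * dt + gdW)
    # heun_stratonovich, multi noise
    yp <- y + f(t, y) * dt + gdW
    Gp <- g(t + dt, yp)
    return(y + 0.5 * (f(t, y) + f(t + dt, yp)) * dt +
             0.5 * as.numeric((G + Gp) %*% dW))
  }
  gv <- g(t, y)
  if (method == "euler_maruyama") {
    y + f(t, y) * dt + gv * dW
  } else if (method == "milstein") {
    dgv <- if (!is.null(dg)) dg(t, y) else {
      h <- 1e-6 * pmax(1, abs(y))
      (g(t, y + h) - g(t, y - h)) / (2 * h)
    }
    y + f(t, y) * dt + gv * dW + 0.5 * gv * dgv * (dW^2 - dt)
  } else {                             # heun_stratonovich
    yp <- y + f(t, y) * dt + gv * dW
    y + 0.5 * (f(t, y) + f(t + dt, yp)) * dt +
      0.5 * (gv + g(t + dt, yp)) * dW
  }
}
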