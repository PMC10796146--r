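test_that("explicit RK steps match hand-evaluated stages", {
  f <- function(t, y) -y
  expect_equal(ode_step(f, 1, 0, 0.1, "euler"), 0.9)
  # four-stage RK4 evaluation, frozen from an independent hand computation:
  # k1 = -1, k2 = -0.95, k3 = -0.9525, k4 = -0.90475
  expect_equal(ode_step(f, 1, 0, 0.1, "rk4"), 0.9048375, tolerance = 1e-12)
  # dy/dt = 0 leaves the state unchanged for every method
  z <- function(t, y) 0 * y
  for (m in c("euler", "midpoint", "heun", "rk3", "rk4"))
    expect_identical(ode_step(z, c(1, 2), 0, 0.1, m), c(1, 2))
})

test_that("tableau validation rejects inconsistent schemes and a registered RK4 reproduces the built-in", {
  expect_error(make_tableau(matrix(0, 1, 1), b = 0.9, c = 0, order = 1),
               "sum\\(b\\)")
  expect_error(make_tableau(rbind(c(0, 0), c(0.4, 0)), b = c(0.5, 0.5),
                            c = c(0, 0.5), order = 2), "row sums")
  expect_error(make_tableau(matrix(1, 1, 1), b = 1, c = 1, order = 1),
               "lower triangular")
  tb <- make_tableau(rbind(c(0, 0, 0, 0), c(0.5, 0, 0, 0),
                           c(0, 0.5, 0, 0), c(0, 0, 1, 0)),
                     b = c(1, 2, 2, 1) / 6, c = c(0, 0.5, 0.5, 1),
                     order = 4)
  register_tableau("rk4_user", tb)
  f <- function(t, y) sin(y) - 0.3 * y
  y <- c(0.7, -1.2)
  expect_identical(ode_step(f, y, 0, 0.05, "rk4_user"),
                   ode_step(f, y, 0, 0.05, "rk4"))
})

test_that("empirical convergence orders match scheme orders", {
  f <- function(t, y) -y
  glob_err <- function(method, dt) {
    y <- 1
    for (k in seq_len(round(1 / dt)))
      y <- ode_step(f, y, (k - 1) * dt, dt, method)
    abs(y - exp(-1))
  }
  dts <- c(0.1, 0.05, 0.025, 0.0125)
  slope <- function(method) {
    errs <- vapply(dts, function(d) glob_err(method, d), numeric(1))
    unname(coef(lm(log(errs) ~ log(dts)))[2])
  }
  expect_equal(slope("euler"), 1, tolerance = 0.1)
  expect_equal(slope("midpoint"), 2, tolerance = 0.15 / 2)
  expect_equal(slope("heun"), 2, tolerance = 0.15 / 2)
  expect_equal(slope("rk4"), 4, tolerance = 0.3 / 4)
})

test_that("exponential Euler is exact on linear-affine equations", {
  # dy/dt = -y/tau: one step equals the closed form to machine precision
  y1 <- ode_step_exp_euler(-1 / 10, NULL, 1, 0, 1)
  expect_equal(y1, exp(-0.1), tolerance = 1e-15)
  # a = 0, r = 0: unchanged
  expect_equal(ode_step_exp_euler(0, NULL, 2.5, 0, 0.7), 2.5)
  # exact on any dy/dt = a*y + c over many random instances
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, -2, 2); cc <- runif(1, -3, 3)
    y0 <- runif(1, -2, 2); dt <- runif(1, 0.01, 1)
    y <- ode_step_exp_euler(a, function(t, y) cc, y0, 0, dt)
    exact <- if (abs(a) < 1e-12) y0 + cc * dt
             else (y0 + cc / a) * exp(a * dt) - cc / a
    expect_equal(y, exact, tolerance = 1e-12)
  }
  # LIF subthreshold trajectory matches the closed-form relaxation
  tau <- 10; R <- 1; I <- 5; V <- 0
  for (k in 1:100)
    V <- ode_step_exp_euler(-1 / tau, function(t, y) R * I / tau, V, 0, 0.1)
  exact <- R * I * (1 - exp(-10 / tau))
  expect_equal(V, exact, tolerance = 1e-12)
})

test_that("adaptive stepper controls error and degrades to fixed-step", {
  f <- function(t, y) -y
  # zero error estimate (both orders exact on dy/dt = 0) grows dt to clip
  st <- ode_step_adaptive(function(t, y) 0 * y, 1, 0, 0.1, dt_max = 0.3)
  expect_true(st$accepted)
  expect_equal(st$dt, 0.3)
  # tight rtol: global error below tolerance x 10
  sol <- ode_solve_adaptive(f, 1, 0, 1, 0.05, rtol = 1e-8, atol = 1e-12)
  expect_lt(abs(sol$y[length(sol$t)] - exp(-1)), 1e-7)
  # dt_min = dt_max forces the higher-order member at fixed step
  h <- 0.05
  fixed <- ode_solve_adaptive(f, 1, 0, 1, h, dt_min = h, dt_max = h)
  y <- 1
  for (k in 1:20) y <- ode_step(f, y, (k - 1) * h, h, "rkf45")
  expect_equal(fixed$y[length(fixed$t)], y, tolerance = 1e-14)
  expect_error(ode_step_adaptive(f, 1, 0, 1e-13, dt_min = 1e-6),
               "stiffness")
})

test_that("SDE steppers reduce to deterministic schemes when g = 0", {
  f <- function(t, y) 2 * y
  g0 <- function(t, y) 0 * y
  y <- c(1, -0.5)
  for (m in c("euler_maruyama", "milstein", "heun_stratonovich")) {
    out <- sde_step(f, g0, y, 0, 0.1, c(0.3, -0.2), m)
    det <- if (m == "heun_stratonovich")
      y + 0.5 * (f(0, y) + f(0.1, y + f(0, y) * 0.1)) * 0.1
    else y + f(0, y) * 0.1
    expect_equal(out, det, tolerance = 1e-14)
  }
  expect_error(sde_step(f, function(t, y) matrix(1, 2, 2), y, 0, 0.1,
                        c(0.1, 0.2), "milstein", wiener = "multi"),
               "unsupported")
})

test_that("Ornstein-Uhlenbeck sampling reaches the analytic stationary variance", {
  theta <- 1; sig <- 0.5; dt <- 0.01
  n_paths <- 8000L
  set.seed(99)
  y <- rnorm(n_paths, 0, sqrt(sig^2 / (2 * theta)))   # start at stationarity
  f <- function(t, y) -theta * y
  g <- function(t, y) rep(sig, length(y))
  for (k in 1:1200)
    y <- sde_step(f, g, y, 0, dt, rnorm(n_paths, sd = sqrt(dt)),
                  "euler_maruyama")
  v_target <- sig^2 / (2 * theta)
  # Monte-Carlo CI (4 sigma) plus the O(theta*dt/2) discretization bias
  ci <- 4 * v_target * sqrt(2 / n_paths) + v_target * theta * dt
  expect_lt(abs(var(y) - v_target), ci)
})

test_that("strong convergence orders on geometric Brownian motion", {
  mu <- 1; sig <- 0.5; X0 <- 1; Tend <- 1
  n_paths <- 200L; n_fine <- 2L^9
  set.seed(7)
  dWf <- matrix(rnorm(n_paths * n_fine, sd = sqrt(Tend / n_fine)),
                n_paths, n_fine)
  X_exact <- X0 * exp((mu - sig^2 / 2) * Tend + sig * rowSums(dWf))
  f <- function(t, y) mu * y
  g <- function(t, y) sig * y
  dg <- function(t, y) rep(sig, length(y))
  strong_slope <- function(method) {
    errs <- c(); hs <- c()
    for (lev in 4:8) {
      n <- 2L^lev; h <- Tend / n; agg <- n_fine / n
      X <- rep(X0, n_paths)
      for (k in seq_len(n)) {
        dW <- rowSums(dWf[, ((k - 1) * agg + 1):(k * agg), drop = FALSE])
        X <- sde_step(f, g, X, (k - 1) * h, h, dW, method, dg = dg)
      }
      errs <- c(errs, mean(abs(X - X_exact))); hs <- c(hs, h)
    }
    unname(coef(lm(log(errs) ~ log(hs)))[2])
  }
  expect_equal(strong_slope("euler_maruyama"), 0.5, tolerance = 0.1 / 0.5)
  expect_equal(strong_slope("milstein"), 1.0, tolerance = 0.15)
})

test_that("Ito and Stratonovich schemes on common noise differ by the drift correction", {
  mu <- 1; sig <- 0.5
  f <- function(t, y) mu * y
  g <- function(t, y) sig * y
  set.seed(21)
  n_paths <- 4000L; n <- 400L; h <- 1 / n
  X1 <- rep(1, n_paths); X2 <- rep(1, n_paths)
  for (k in seq_len(n)) {
    dW <- rnorm(n_paths, sd = sqrt(h))
    X1 <- sde_step(f, g, X1, 0, h, dW, "euler_maruyama")
    X2 <- sde_step(f, g, X2, 0, h, dW, "heun_stratonovich")
  }
  # E[log X] differs by sig^2/2 between the two integral conventions
  expect_equal(mean(log(X2)) - mean(log(X1)), sig^2 / 2, tolerance = 0.15)
})
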