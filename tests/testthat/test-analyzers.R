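test_that("phase plane recovers a diagonal linear system exactly", {
  x0 <- c(0.7, -0.4)
  A <- diag(c(-1, -2))
  f <- function(y) as.numeric(A %*% (y - x0))
  pp <- phase_plane_2d(f, c(-2, 2), c(-2, 2), n_grid = 30)
  expect_length(pp$fixed_points, 1L)
  fp <- pp$fixed_points[[1]]
  expect_equal(fp$x, x0, tolerance = 1e-8)
  expect_equal(sort(Re(fp$eigenvalues)), c(-2, -1), tolerance = 1e-6)
  expect_identical(fp$label, "stable")
  # nullclines of component 1 lie on x = x0[1]
  expect_lt(max(abs(pp$nullclines[[1]]$x - x0[1])), 1e-8)
})

test_that("FHN fixed point and Jacobian match the analytic oracle to 1e-6", {
  oracle <- fhn_fixed_points()[[1]]
  pp <- phase_plane_2d(fhn_vector_field(), c(-3, 3), c(-2, 3), n_grid = 40,
                       tol = 1e-8)
  expect_length(pp$fixed_points, 1L)
  fp <- pp$fixed_points[[1]]
  expect_lt(max(abs(fp$x - oracle$x)), 1e-6)
  expect_lt(max(abs(sort(Re(fp$eigenvalues)) - sort(Re(oracle$eigenvalues)))),
            1e-6)
  expect_identical(fp$label, "stable")
  # finite-difference Jacobian matches [[1-v^2, -1], [1/tau, -b/tau]]
  lin <- linearize(fhn_vector_field(), fp$x)
  expect_lt(max(abs(lin$jacobian - oracle$jacobian)), 1e-6)
})

test_that("decision-model fixed points are symmetric with odd count", {
  pp <- phase_plane_2d(decision_vector_field(mu0 = 0), c(0, 1), c(0, 1),
                       n_grid = 40, tol = 1e-9)
  n_fp <- length(pp$fixed_points)
  expect_gte(n_fp, 3L)
  expect_equal(n_fp %% 2L, 1L)
  locs <- t(vapply(pp$fixed_points, `[[`, numeric(2), "x"))
  # for every fixed point, its swap is also a fixed point
  for (i in seq_len(n_fp)) {
    sw <- rev(locs[i, ])
    expect_lt(min(sqrt(rowSums(sweep(locs, 2, sw)^2))), 1e-6)
  }
})

test_that("50 random 2D linear systems are recovered to 1e-8", {
  for (s in 1:50) {
    inst <- random_linear_2d(seed = s)
    pp <- phase_plane_2d(inst$f, c(-3, 3), c(-3, 3), n_grid = 12)
    expect_length(pp$fixed_points, 1L)
    fp <- pp$fixed_points[[1]]
    expect_lt(max(abs(fp$x - inst$x0)), 1e-8)
    expect_lt(max(abs(sort(Re(fp$eigenvalues)) - sort(Re(inst$eigenvalues)))),
              1e-8)
    expect_identical(fp$label, "stable")
  }
})

test_that("FHN Iext scan brackets the analytic Hopf onset and refines with the grid", {
  # eigenvalue-crossing oracle: trace zero at 1 - v*^2 = b/tau
  a <- 0.7; b <- 0.8; tau <- 12.5
  v_h <- -sqrt(1 - b / tau)
  I_hopf <- -v_h + v_h^3 / 3 + (v_h + a) / b
  make_f <- function(Iext) fhn_vector_field(Iext = Iext)
  box <- list(c(-3, 3), c(-2, 4))
  br1 <- bifurcation_scan(make_f, list(Iext = seq(0, 2, by = 0.01)),
                          state_box = box, n_starts = 4)
  expect_gte(nrow(br1$change_points), 1L)
  onset <- br1$change_points[1, ]
  expect_true(onset$lo <= I_hopf && I_hopf <= onset$hi)
  expect_identical(onset$from, "stable")
  br2 <- bifurcation_scan(make_f, list(Iext = seq(0.2, 0.5, by = 0.005)),
                          state_box = box, n_starts = 4)
  onset2 <- br2$change_points[1, ]
  expect_true(onset2$lo <= I_hopf && I_hopf <= onset2$hi)
  expect_lt(onset2$hi - onset2$lo, onset$hi - onset$lo)
})

test_that("a pure relaxation system yields zero stability changes", {
  make_f <- function(k) function(y) -k * (y - c(0.5, -0.5))
  br <- bifurcation_scan(make_f, list(k = seq(0.5, 3, by = 0.25)),
                         state_box = list(c(-2, 2), c(-2, 2)),
                         n_starts = 3)
  expect_equal(nrow(br$change_points), 0L)
  expect_true(all(br$points$label == "stable"))
})

test_that("a codim-1 slice of a codim-2 scan equals the 1D scan", {
  make_f <- function(Iext, a) fhn_vector_field(Iext = Iext, a = a)
  box <- list(c(-3, 3), c(-2, 4))
  grid_I <- seq(0, 1, by = 0.1)
  br2d <- bifurcation_scan(make_f, list(Iext = grid_I, a = c(0.7, 1.0)),
                           state_box = box, n_starts = 4)
  br1d <- bifurcation_scan(function(Iext) make_f(Iext, 0.7),
                           list(Iext = grid_I), state_box = box,
                           n_starts = 4)
  slice <- br2d$points[br2d$points$a == 0.7, c("Iext", "s1", "s2", "max_re",
                                               "label")]
  rownames(slice) <- NULL
  ref <- br1d$points[, c("Iext", "s1", "s2", "max_re", "label")]
  expect_equal(slice, ref, tolerance = 1e-10)
})

test_that("slow-point finder locates unique roots, dedupes, and is order invariant", {
  sys <- random_linear_system(6, spectral_bound = 2, seed = 3)
  F <- function(x) as.numeric(sys$A %*% x) - sys$b
  x_star <- solve(sys$A, sys$b)
  set.seed(8)
  seeds <- matrix(rnorm(5 * 6, sd = 3), 5, 6)
  sp <- find_slow_points(F, seeds, tol = 1e-8)
  expect_length(sp$points, 1L)
  expect_equal(sp$points[[1]]$x, x_star, tolerance = 1e-6)
  expect_lte(sp$points[[1]]$residual, 1e-8)
  # duplicate seeds collapse to a single deduplicated point
  sp2 <- find_slow_points(F, rbind(seeds[1, ], seeds[1, ]), tol = 1e-8)
  expect_length(sp2$points, 1L)
  # seed-order invariance
  sp3 <- find_slow_points(F, seeds[5:1, ], tol = 1e-8)
  expect_equal(sp3$points[[1]]$x, sp$points[[1]]$x, tolerance = 1e-9)
  # gradient-descent optimizer reaches the same root on a gentle system
  sysg <- list(A = diag(c(-1, -0.5)), b = c(0.3, -0.2))
  Fg <- function(x) as.numeric(sysg$A %*% x) - sysg$b
  spg <- find_slow_points(Fg, matrix(c(2, 2), 1), tol = 1e-8,
                          optimizer = "gd", max_iter = 2000)
  expect_length(spg$points, 1L)
  expect_equal(spg$points[[1]]$x, solve(sysg$A, sysg$b), tolerance = 1e-6)
  # every accepted point satisfies the residual bound by construction
  for (p in c(sp$points, spg$points)) expect_lte(max(abs(p$residual)), 1e-8)
  # all seeds diverging yields an empty result with a diagnostic
  sp_empty <- find_slow_points(function(x) x * 0 + 1,
                               matrix(0, 1, 2), tol = 1e-8)
  expect_length(sp_empty$points, 0L)
  expect_match(sp_empty$diagnostic, "no seed")
})

test_that("linearization of F(x) = -x gives -I with unit negative spectrum", {
  lin <- linearize(function(x) -x, c(0.3, -0.8, 2))
  expect_equal(lin$jacobian, -diag(3), tolerance = 1e-8)
  expect_equal(Re(lin$eigenvalues), rep(-1, 3), tolerance = 1e-8)
  expect_identical(lin$label, "stable")
  expect_identical(linearize(function(x) x, c(1, 1))$label, "unstable")
  expect_identical(linearize(function(x) 0 * x, c(1, 1))$label, "marginal")
})
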