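# Synthetic instance generators: chaotic task series and random operator /
# analyzer instances. Everything is a pure function of its spec + seed.

#' Lorenz attractor trajectory
#'
#' Integrates the Lorenz system
#' `dx = sigma(y - x); dy = x(rho - z) - y; dz = xy - beta z`
#' with the package's own fixed-step rk4. Defaults (sigma 10, rho 28,
#' beta 8/3) lie in the chaotic regime.
#'
#' @param sigma,rho,beta Lorenz parameters.
#' @param dt integration step in Lorenz time units (<= 0.02 for rk4
#'   stability).
#' @param duration total time units.
#' @param init initial state `c(x, y, z)`.
#' @param seed optional integer; when supplied, jitters the initial state
#'   by `U(-0.1, 0.1)` per coordinate (deterministically).
#' @return numeric matrix `[T x 3]` with columns `x`, `y`, `z` (the initial
#'   state is row 1).
#' @export
lorenz_series <- function(sigma = 10, rho = 28, beta = 8 / 3,
                          dt = 0.01, duration = 60,
                          init = c(1, 1, 1), seed = NULL) {
  if (dt > 0.02)
    stop("parameter error: dt must be <= 0.02 for rk4 stability",
         call. = FALSE)
  y <- as.numeric(init)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    y <- y + runif(3, -0.1, 0.1)
  }
  f <- function(t, s)
    c(sigma * (s[2L] - s[1L]),
      s[1L] * (rho - s[3L]) - s[2L],
      s[1L] * s[2L] - beta * s[3L])
  n <- as.integer(round(duration / dt))
  out <- matrix(0, n + 1L, 3L, dimnames = list(NULL, c("x", "y", "z")))
  out[1L, ] <- y
  for (k in seq_len(n)) {
    y <- ode_step(f, y, (k - 1L) * dt, dt, "rk4")
    if (any(!is.finite(y)))
      stop("parameter error: Lorenz integration diverged at step ", k,
           call. = FALSE)
    out[k + 1L, ] <- y
  }
  out
}

#' Random CSR connectivity instance
#'
#' @param n_pre,n_post shape.
#' @param density edge probability in `[0, 1]`.
#' @param weight_law `"normal"` (standard normal weights), `"uniform"`
#'   (U(0,1)), or a single number for homogeneous weights.
#' @param seed integer seed.
#' @return a `csr_matrix`.
#' @export
random_csr <- function(n_pre, n_post, density, weight_law = "normal",
                       seed = 1L) {
  if (density < 0 || density > 1)
    stop("parameter error: density must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  keep <- runif(n_pre * n_post) < density
  idx <- which(keep) - 1L
  rows <- idx %/% n_post + 1L
  cols <- idx %% n_post
  nnz <- length(idx)
  data <- if (is.numeric(weight_law)) rep(weight_law, nnz)
          else switch(weight_law,
                      normal = rnorm(nnz),
                      uniform = runif(nnz),
                      stop("unknown weight law: ", weight_law,
                           call. = FALSE))
  csr_matrix(data, cols, c(0L, cumsum(tabulate(rows, nbins = n_pre))),
             c(n_pre, n_post))
}

#' Random linear system with bounded spectrum
#'
#' Draws `A` with iid normal entries rescaled so its spectral radius equals
#' `spectral_bound`, plus a random offset `b`; the unique equilibrium of
#' `dx/dt = A(x - x0)` systems built from it is `x0 = A^-1 b` for
#' `F(x) = A x - b`.
#'
#' @param dim state dimension.
#' @param spectral_bound target spectral radius of `A`.
#' @param seed integer seed.
#' @return list with `A`, `b`.
#' @export
random_linear_system <- function(dim, spectral_bound = 0.9, seed = 1L) {
  set.seed(as.integer(seed))
  A <- matrix(rnorm(dim * dim), dim, dim)
  rad <- max(Mod(eigen(A, only.values = TRUE)$values))
  A <- A * (spectral_bound / rad)
  list(A = A, b = rnorm(dim))
}

#' Random stable 2D linear vector field (analyzer oracle instance)
#'
#' `F(x) = A (x - x0)` with eigenvalues of `A` having negative real part.
#'
#' @param seed integer seed.
#' @return list with `A`, `x0`, `f` (the closure), `eigenvalues`.
#' @export
random_linear_2d <- function(seed = 1L) {
  set.seed(as.integer(seed))
  repeat {
    A <- matrix(rnorm(4, sd = 1.5), 2, 2)
    ev <- eigen(A, only.values = TRUE)$values
    if (all(Re(ev) < -0.05)) break
  }
  x0 <- runif(2, -1.5, 1.5)
  list(A = A, x0 = x0,
       f = function(y) as.numeric(A %*% (y - x0)),
       eigenvalues = ev)
}
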