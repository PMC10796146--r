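# Modeling toolbox: connectivity builders, weight initializers, stimulus
# constructors, and basic activity measures.

#' Fixed-probability random connectivity
#'
#' Each ordered (pre, post) pair is connected independently with probability
#' `p`. Sampling uses the same per-row Lehmer stream as [jitconn_spec()], so
#' a matrix-free JIT operator and this materialized connector agree exactly
#' for equal seeds. Column indices are sorted within each row.
#'
#' @param n_pre,n_post population sizes.
#' @param p connection probability in `[0, 1]`.
#' @param seed integer seed.
#' @param include_self keep self-pairs `(i, i)` when `n_pre == n_post`
#'   (default `TRUE`).
#' @param weight homogeneous scalar weight (default 1).
#' @return a `csr_matrix`.
#' @export
fixed_prob_conn <- function(n_pre, n_post, p, seed, include_self = TRUE,
                            weight = 1) {
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("parameter error: p must lie in [0, 1]", call. = FALSE)
  m <- jitconn_materialize(jitconn_spec(n_pre, n_post, p, seed, weight))
  if (!include_self && n_pre == n_post && csr_nnz(m) > 0L) {
    rows <- csr_row_ids(m)
    keep <- m$indices != rows - 1L
    m <- csr_matrix(
      data = if (length(m$data) == 1L) m$data else m$data[keep],
      indices = m$indices[keep],
      indptr = c(0L, cumsum(tabulate(rows[keep], nbins = m$shape[1L]))),
      shape = m$shape)
  }
  m
}

#' All-to-all connectivity
#' @inheritParams fixed_prob_conn
#' @return a `csr_matrix` with homogeneous weight.
#' @export
all2all_conn <- function(n_pre, n_post, include_self = TRUE, weight = 1) {
  rows <- lapply(seq_len(n_pre) - 1L, function(r) {
    cols <- 0:(n_post - 1L)
    if (!include_self && n_pre == n_post) cols <- cols[cols != r]
    cols
  })
  lens <- lengths(rows)
  csr_matrix(weight, unlist(rows), c(0L, cumsum(lens)), c(n_pre, n_post))
}

#' One-to-one connectivity
#' @param n population size; `weight` homogeneous scalar.
#' @param weight homogeneous scalar weight.
#' @return a `csr_matrix` mapping neuron i to neuron i.
#' @export
one2one_conn <- function(n, weight = 1) {
  csr_matrix(weight, 0:(n - 1L), 0:n, c(n, n))
}

#' Translation-invariant Gaussian ring kernel
#'
#' `w[i, j] = J0/(sqrt(2*pi)*a) * exp(-d(x_i, x_j)^2 / (2*a^2))` with `d`
#' the circular distance on a ring of length `L`; neurons sit at
#' `x_i = -L/2 + L*(i-1)/n`.
#'
#' @param n number of neurons on the ring (>= 3).
#' @param J0 kernel peak scale.
#' @param a kernel width (> 0), same units as `L`.
#' @param L ring length (default `2*pi`).
#' @return dense `n x n` weight matrix.
#' @export
ring_gaussian_weights <- function(n, J0, a, L = 2 * pi) {
  stopifnot(n >= 3, a > 0, L > 0)
  x <- ring_positions(n, L)
  d <- outer(x, x, function(xi, xj) {
    dd <- abs(xi - xj)
    pmin(dd, L - dd)
  })
  J0 / (sqrt(2 * pi) * a) * exp(-d^2 / (2 * a^2))
}

#' Neuron positions on a ring of length L
#' @param n number of neurons; `L` ring length.
#' @param L ring length.
#' @export
ring_positions <- function(n, L = 2 * pi) -L / 2 + L * (seq_len(n) - 1L) / n

#' Piecewise-constant (section) input
#'
#' @param values numeric segment values.
#' @param durations segment durations, ms (positive, same length).
#' @param dt step, ms.
#' @return numeric vector of length `sum(round(durations/dt))`.
#' @export
section_input <- function(values, durations, dt) {
  stopifnot(length(values) == length(durations), dt > 0)
  if (!length(values)) return(numeric())
  if (any(durations <= 0))
    stop("durations must be positive", call. = FALSE)
  rep.int(as.numeric(values), as.integer(round(durations / dt)))
}

#' Homogeneous Poisson spike raster
#'
#' Independent Bernoulli(`rate * dt / 1000`) per time bin and channel.
#'
#' @param rate firing rate, Hz.
#' @param n_channels number of independent channels.
#' @param duration total time, ms.
#' @param dt bin width, ms.
#' @param seed integer seed.
#' @return logical matrix `[steps x n_channels]`.
#' @export
poisson_spikes <- function(rate, n_channels, duration, dt, seed) {
  p <- rate * dt / 1000
  if (p >= 1)
    stop("parameter error: rate*dt/1000 must be < 1 (got ", p, ")",
         call. = FALSE)
  steps <- as.integer(ceiling(duration / dt - 1e-9))
  set.seed(as.integer(seed))
  matrix(runif(steps * n_channels) < p, steps, n_channels)
}

#' Population firing rate in a moving window
#'
#' `rate(t) = spike count in (t - window, t] / (n * window)`, rescaled to
#' Hz; before `t = window` the count is normalized by the elapsed time, so a
#' population firing every bin reads a constant `1000/dt` Hz from the first
#' sample.
#'
#' @param spikes logical matrix `[steps x n]`.
#' @param window window length, ms (>= dt).
#' @param dt bin width, ms.
#' @return numeric rate trace, Hz, one value per step.
#' @export
firing_rate <- function(spikes, window, dt) {
  if (window < dt)
    stop("parameter error: window must be >= dt", call. = FALSE)
  spikes <- as.matrix(spikes)
  n <- ncol(spikes)
  w <- max(1L, as.integer(round(window / dt)))
  counts <- rowSums(spikes)
  cs <- cumsum(counts)
  lag <- c(rep(0, w), head(cs, -w))
  inwin <- cs - lag
  eff <- pmin(seq_along(cs), w)          # partial windows near t = 0
  1000 * inwin / (n * eff * dt)
}

#' Export a spike raster as a two-column event table
#' @param spikes logical matrix `[steps x n]`; `dt` bin width ms.
#' @param dt bin width, ms.
#' @return data.frame `time_ms`, `neuron_id` (0-based), in time order.
#' @export
spikes_to_events <- function(spikes, dt) {
  idx <- which(spikes, arr.ind = TRUE)
  o <- order(idx[, 1L], idx[, 2L])
  data.frame(time_ms = idx[o, 1L] * dt, neuron_id = idx[o, 2L] - 1L)
}

# ---- weight initializers ---------------------------------------------------

#' Weight initializers
#'
#' `init_constant` fills with a value; `init_uniform` draws from
#' `U(low, high)`; `init_normal` from `N(mean, sd)`. All are seeded.
#'
#' @param n number of weights.
#' @param value,low,high,mean,sd distribution parameters.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
init_constant <- function(n, value) rep.int(as.numeric(value), n)

#' @rdname init_constant
#' @export
init_uniform <- function(n, low = 0, high = 1, seed = 1L) {
  set.seed(as.integer(seed))
  runif(n, low, high)
}

#' @rdname init_constant
#' @export
init_normal <- function(n, mean = 0, sd = 1, seed = 1L) {
  set.seed(as.integer(seed))
  rnorm(n, mean, sd)
}
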