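# Echo-state reservoir training: offline ridge regression and online
# FORCE / recursive least squares readouts.

#' Echo-state reservoir specification
#'
#' The recurrent matrix is sparse normal, rescaled so that its spectral
#' radius (largest eigenvalue magnitude) equals `spectral_radius` within
#' 1e-6; input weights are uniform in `[-input_scale, input_scale]`. State
#' recursion: `x[t+1] = (1 - leak)*x[t] + leak*tanh(W_rec x[t] + W_in u[t])`.
#'
#' @param n reservoir units.
#' @param d_in input dimension.
#' @param spectral_radius target spectral radius of the recurrent matrix.
#' @param input_scale input weight scale.
#' @param leak_rate leak in `(0, 1]` (1 = plain tanh recursion).
#' @param density recurrent connection density.
#' @param seed integer seed; the realized matrices are pure functions of the
#'   spec.
#' @return object of class `"reservoir_params"` carrying `W_rec` (a
#'   `dgCMatrix`) and `W_in`.
#' @export
reservoir_params <- function(n = 400L, d_in = 3L, spectral_radius = 0.9,
                             input_scale = 0.5, leak_rate = 0.3,
                             density = 0.02, seed = 1L) {
  stopifnot(leak_rate > 0, leak_rate <= 1, density >= 0, density <= 1)
  set.seed(as.integer(seed))
  nnz <- max(1L, round(density * n * n))
  idx <- sample.int(n * n, nnz)
  W <- Matrix::sparseMatrix(i = ((idx - 1L) %% n) + 1L,
                            j = ((idx - 1L) %/% n) + 1L,
                            x = rnorm(nnz), dims = c(n, n))
  ev <- eigen(as.matrix(W), only.values = TRUE)$values
  rad <- max(Mod(ev))
  if (rad == 0)
    stop("parameter error: recurrent matrix has zero spectral radius",
         call. = FALSE)
  W <- W * (spectral_radius / rad)
  W_in <- matrix(runif(n * d_in, -input_scale, input_scale), n, d_in)
  structure(list(n = as.integer(n), d_in = as.integer(d_in),
                 spectral_radius = spectral_radius,
                 input_scale = input_scale, leak_rate = leak_rate,
                 density = density, seed = as.integer(seed),
                 W_rec = W, W_in = W_in),
            class = "reservoir_params")
}

#' Drive a reservoir with an input series and collect its states
#'
#' @param params a [reservoir_params()].
#' @param input numeric matrix `[T x d_in]`.
#' @param x0 initial state (default zeros).
#' @return state matrix `[T x n]`; row t is the state after absorbing
#'   input row t.
#' @export
reservoir_collect <- function(params, input, x0 = NULL) {
  stopifnot(inherits(params, "reservoir_params"))
  input <- as.matrix(input)
  if (ncol(input) != params$d_in)
    stop("input has ", ncol(input), " columns, expected ", params$d_in,
         call. = FALSE)
  if (any(!is.finite(input))) stop("non-finite inputs", call. = FALSE)
  n <- params$n
  leak <- params$leak_rate
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  TT <- nrow(input)
  out <- matrix(0, TT, n)
  Wr <- params$W_rec
  Wi <- params$W_in
  for (t in seq_len(TT)) {
    x <- (1 - leak) * x +
      leak * tanh(as.numeric(Wr %*% x) + as.numeric(Wi %*% input[t, ]))
    out[t, ] <- x
  }
  out
}

#' Ridge-regression readout fit
#'
#' Solves `W = (X'X + lambda I)^-1 X'Y` through a Cholesky factorization.
#' At `lambda = 0` with a rank-deficient design a warning is raised and the
#' least-norm solution (via the pseudoinverse) is returned.
#'
#' @param states design matrix `[T x N]`.
#' @param targets target matrix `[T x d_out]`.
#' @param lambda nonnegative regularization.
#' @return weight matrix `[N x d_out]`.
#' @export
ridge_fit <- function(states, targets, lambda = 0) {
  X <- as.matrix(states)
  Y <- as.matrix(targets)
  stopifnot(nrow(X) == nrow(Y), lambda >= 0)
  G <- crossprod(X)
  if (lambda > 0) diag(G) <- diag(G) + lambda
  XtY <- crossprod(X, Y)
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular system at lambda = 0; returning least-norm solution",
            call. = FALSE)
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1L]
    W <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    return(W)
  }
  backsolve(ch, forwardsolve(t(ch), XtY))
}

#' Regularized least-squares loss of a readout
#' @param W weights `[N x d_out]`; `states`, `targets`, `lambda` as in
#'   [ridge_fit()].
#' @param states design matrix.
#' @param targets target matrix.
#' @param lambda regularization.
#' @export
ridge_loss <- function(W, states, targets, lambda = 0) {
  R <- states %*% W - targets
  sum(R^2) + lambda * sum(W^2)
}

#' Initialize recursive least squares (FORCE) state
#'
#' @param n feature dimension.
#' @param d_out output dimension.
#' @param alpha initialization scale; `P0 = I/alpha`.
#' @return object of class `"rls_state"` with `P` and `W`.
#' @export
rls_init <- function(n, d_out = 1L, alpha = 1) {
  stopifnot(alpha > 0)
  structure(list(P = diag(1 / alpha, n), W = matrix(0, n, d_out),
                 alpha = alpha),
            class = "rls_state")
}

#' One FORCE / recursive-least-squares update
#'
#' `k = P x / (1 + x'P x)`; `e = W'x - y`; `W <- W - k e'`;
#' `P <- P - (P x)(P x)' / (1 + x'P x)`. The rank-1 downdate is formed as a
#' symmetric outer product, so `P` stays exactly symmetric in floating
#' point.
#'
#' @param rls an [rls_init()] state.
#' @param x feature vector (length n).
#' @param y_target target vector (length d_out).
#' @return the updated state (also modified copy returned; reassign it).
#' @export
force_step <- function(rls, x, y_target) {
  stopifnot(inherits(rls, "rls_state"))
  Px <- as.numeric(rls$P %*% x)
  denom <- 1 + sum(x * Px)
  k <- Px / denom
  e <- as.numeric(crossprod(rls$W, x)) - as.numeric(y_target)
  W <- rls$W - outer(k, e)
  P <- rls$P - tcrossprod(Px) / denom
  if (any(!is.finite(W)) || any(!is.finite(P)))
    stop("divergence error: non-finite FORCE update", call. = FALSE)
  structure(list(P = P, W = W, alpha = rls$alpha), class = "rls_state")
}

#' Run FORCE over a state/target series (single online pass)
#' @param states `[T x N]`; `targets` `[T x d_out]`; `alpha` P0 scale.
#' @param targets target matrix.
#' @param alpha initialization scale for `P0 = I/alpha`.
#' @return final `rls_state`.
#' @export
force_train <- function(states, targets, alpha = 1) {
  X <- as.matrix(states)
  Y <- as.matrix(targets)
  n <- ncol(X)
  # same update algebra as force_step, kept inline for the O(T n^2) pass
  P <- diag(1 / alpha, n)
  W <- matrix(0, n, ncol(Y))
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    Px <- as.numeric(P %*% x)
    denom <- 1 + sum(x * Px)
    e <- as.numeric(crossprod(W, x)) - Y[t, ]
    W <- W - outer(Px / denom, e)
    P <- P - tcrossprod(Px) / denom
  }
  if (any(!is.finite(W)))
    stop("divergence error: non-finite FORCE update", call. = FALSE)
  structure(list(P = P, W = W, alpha = alpha), class = "rls_state")
}

#' Train an echo-state readout on chaotic-series one-step prediction
#'
#' Protocol: generate the task series (Lorenz attractor via
#' [lorenz_series()]), standardize each variable using training-split
#' statistics, drive the reservoir with the standardized series, discard the
#' washout, fit the readout to predict the next-step standardized state
#' (teacher-forced), and report the mean squared error over the held-out
#' split (averaged over variables and test steps, standardized scale).
#'
#' @param task `"lorenz_prediction"`.
#' @param method `"ridge"` or `"force"`.
#' @param params a [reservoir_params()] (with `d_in = 3`).
#' @param lambda ridge regularization (ridge method).
#' @param alpha RLS initialization scale (force method).
#' @param duration task series length in model time units (default 60).
#' @param dt task series step (default 0.01).
#' @param washout_frac initial fraction discarded (default 0.1).
#' @param train_frac fraction of the remainder used for training
#'   (default 0.7).
#' @param series optional precomputed `[T x 3]` series overriding the task
#'   generator.
#' @return list with `weights`, `mse` (test), `train_mse`, and `meta`.
#' @export
train_and_forecast <- function(task = "lorenz_prediction",
                               method = c("ridge", "force"),
                               params = reservoir_params(),
                               lambda = 1e-6, alpha = 1,
                               duration = 60, dt = 0.01,
                               washout_frac = 0.1, train_frac = 0.7,
                               series = NULL) {
  method <- match.arg(method)
  if (task != "lorenz_prediction")
    stop("unknown task: ", task, call. = FALSE)
  if (is.null(series))
    series <- lorenz_series(duration = duration, dt = dt)
  TT <- nrow(series)
  u <- series[-TT, , drop = FALSE]        # inputs
  y <- series[-1L, , drop = FALSE]        # next-step targets
  n_pairs <- nrow(u)
  n_wash <- floor(washout_frac * n_pairs)
  n_train <- floor(train_frac * (n_pairs - n_wash))
  idx_train <- n_wash + seq_len(n_train)
  idx_test <- (n_wash + n_train + 1L):n_pairs
  # standardize per variable from training-split statistics
  mu <- colMeans(u[idx_train, , drop = FALSE])
  sdv <- apply(u[idx_train, , drop = FALSE], 2L, sd)
  us <- sweep(sweep(u, 2L, mu), 2L, sdv, "/")
  ys <- sweep(sweep(y, 2L, mu), 2L, sdv, "/")
  states <- reservoir_collect(params, us)
  feats <- cbind(states, 1)               # readout sees states + bias
  Xtr <- feats[idx_train, , drop = FALSE]
  Ytr <- ys[idx_train, , drop = FALSE]
  Xte <- feats[idx_test, , drop = FALSE]
  Yte <- ys[idx_test, , drop = FALSE]
  W <- if (method == "ridge") ridge_fit(Xtr, Ytr, lambda)
       else force_train(Xtr, Ytr, alpha)$W
  mse <- function(X, Y) mean((X %*% W - Y)^2)
  list(weights = W,
       mse = mse(Xte, Yte),
       train_mse = mse(Xtr, Ytr),
       meta = list(task = task, method = method,
                   reservoir_seed = params$seed, n = params$n,
                   spectral_radius = params$spectral_radius,
                   leak_rate = params$leak_rate,
                   input_scale = params$input_scale,
                   lambda = lambda, alpha = alpha,
                   duration = duration, dt = dt,
                   washout_frac = washout_frac, train_frac = train_frac,
                   n_train = n_train, n_test = length(idx_test)))
}

#' Free-running (generative) forecast from a trained readout
#'
#' Feeds the readout's own predictions back as input; provided for
#' qualitative inspection, not part of the scored protocol.
#'
#' @param params a [reservoir_params()].
#' @param W trained readout `[(n+1) x d]` (bias row last).
#' @param warmup standardized input series used to set the reservoir state.
#' @param horizon steps to generate.
#' @return matrix `[horizon x d]` of standardized predictions.
#' @export
reservoir_generate <- function(params, W, warmup, horizon) {
  st <- reservoir_collect(params, warmup)
  x <- st[nrow(st), ]
  leak <- params$leak_rate
  out <- matrix(0, horizon, ncol(W))
  u <- c(tail(warmup, 1L))
  for (h in seq_len(horizon)) {
    u <- as.numeric(c(x, 1) %*% W)
    out[h, ] <- u
    x <- (1 - leak) * x +
      leak * tanh(as.numeric(params$W_rec %*% x) +
                  as.numeric(params$W_in %*% u))
  }
  out
}
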