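# Automatic dynamics analysis. Low-dimensional systems: nullclines, vector
# fields, fixed points with stability from 2x2 Jacobian eigenvalues, and
# grid-based codimension-1/2 bifurcation scans. High-dimensional systems:
# slow-point search by minimizing q(x) = 0.5*||F(x)||^2, with
# finite-difference linearization around accepted points.

#' Central finite-difference Jacobian
#'
#' @param F vector field `function(x)`.
#' @param x evaluation point.
#' @param h_rel relative step; the per-coordinate step is
#'   `h_rel * max(1, |x_i|)`.
#' @return Jacobian matrix `dF_i/dx_j`.
#' @export
numeric_jacobian <- function(F, x, h_rel = 1e-6) {
  n <- length(x)
  F0 <- F(x)
  J <- matrix(0, length(F0), n)
  for (j in seq_len(n)) {
    h <- h_rel * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (F(xp) - F(xm)) / (2 * h)
  }
  J
}

#' Damped Newton root search
#' @param F vector field; `x0` start; `tol` on `||F||_inf`;
#'   `max_iter` iteration cap.
#' @param x0 starting point.
#' @param tol convergence tolerance on the residual.
#' @param max_iter iteration cap.
#' @return list `x`, `converged`, `residual`.
#' @export
newton_solve <- function(F, x0, tol = 1e-10, max_iter = 60L) {
  x <- as.numeric(x0)
  for (i in seq_len(max_iter)) {
    Fx <- F(x)
    if (any(!is.finite(Fx))) return(list(x = x, converged = FALSE,
                                         residual = Inf))
    if (max(abs(Fx)) <= tol)
      return(list(x = x, converged = TRUE, residual = max(abs(Fx))))
    J <- numeric_jacobian(F, x)
    step <- tryCatch(solve(J, Fx), error = function(e)
      solve(J + diag(1e-8, nrow(J)), Fx))
    # backtrack if the full step does not reduce the residual
    lam <- 1
    nrm0 <- sum(Fx^2)
    repeat {
      xn <- x - lam * step
      Fn <- F(xn)
      if (all(is.finite(Fn)) && (sum(Fn^2) < nrm0 || lam < 1e-4)) break
      lam <- lam / 2
    }
    x <- xn
  }
  Fx <- F(x)
  list(x = x, converged = max(abs(Fx)) <= tol, residual = max(abs(Fx)))
}

#' Linearize a vector field around a point
#'
#' Central finite-difference Jacobian (step scaled per coordinate),
#' eigendecomposition, and a stability label: `"stable"` when
#' `max Re(lambda) < -margin`, `"unstable"` when `> margin`, otherwise
#' `"marginal"` — the margin keeps line-attractor modes honestly labeled.
#'
#' @param F vector field `function(x)`.
#' @param x expansion point (typically an accepted fixed/slow point).
#' @param margin stability margin on `Re(lambda)` (default 1e-3).
#' @param h_rel finite-difference relative step.
#' @return list `jacobian`, `eigenvalues`, `eigenvectors`, `label`.
#' @export
linearize <- function(F, x, margin = 1e-3, h_rel = 1e-6) {
  J <- numeric_jacobian(F, x, h_rel)
  eg <- eigen(J)
  mre <- max(Re(eg$values))
  label <- if (mre < -margin) "stable"
           else if (mre > margin) "unstable"
           else "marginal"
  list(jacobian = J, eigenvalues = eg$values, eigenvectors = eg$vectors,
       label = label)
}

#' Phase-plane analysis of a 2D vector field
#'
#' Computes the vector field on a grid, traces both nullclines by
#' sign-change scanning with 1D root polishing along grid lines, and locates
#' fixed points by Newton iteration multi-started from cells where both
#' components change sign plus a coarse lattice of extra starts; results are
#' deduplicated and classified through [linearize()].
#'
#' @param f vector field `function(y)` with `y = c(x1, x2)` returning
#'   `c(dx1, dx2)`.
#' @param xlim,ylim state-box ranges `c(lo, hi)`.
#' @param n_grid grid resolution per axis (default 50).
#' @param tol fixed-point acceptance tolerance on `||F||_inf`.
#' @param margin stability margin for labels.
#' @return object of class `"phase_plane"`: `grid` (x, y vectors),
#'   `vector_field` (two matrices), `nullclines` (two data.frames of points),
#'   `fixed_points` (list with `x`, `eigenvalues`, `label`, `residual`).
#' @export
phase_plane_2d <- function(f, xlim, ylim, n_grid = 50L, tol = 1e-8,
                           margin = 1e-3) {
  xs <- seq(xlim[1L], xlim[2L], length.out = n_grid)
  ys <- seq(ylim[1L], ylim[2L], length.out = n_grid)
  U <- matrix(0, n_grid, n_grid)
  V <- matrix(0, n_grid, n_grid)
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    d <- f(c(xs[i], ys[j]))
    U[i, j] <- d[1L]; V[i, j] <- d[2L]
  }

  polish_x <- function(comp, M, j) {
    # roots of component `comp` along y = ys[j]
    out <- NULL
    col <- M[, j]
    sc <- which(col[-n_grid] * col[-1L] < 0)
    for (i in sc) {
      r <- tryCatch(stats::uniroot(function(x) f(c(x, ys[j]))[comp],
                                   c(xs[i], xs[i + 1L]), tol = 1e-12),
                    error = function(e) NULL)
      if (!is.null(r)) out <- rbind(out, c(r$root, ys[j]))
    }
    out
  }
  polish_y <- function(comp, M, i) {
    out <- NULL
    row <- M[i, ]
    sc <- which(row[-n_grid] * row[-1L] < 0)
    for (j in sc) {
      r <- tryCatch(stats::uniroot(function(y) f(c(xs[i], y))[comp],
                                   c(ys[j], ys[j + 1L]), tol = 1e-12),
                    error = function(e) NULL)
      if (!is.null(r)) out <- rbind(out, c(xs[i], r$root))
    }
    out
  }
  nullcline <- function(comp, M) {
    pts <- NULL
    for (j in seq_len(n_grid)) pts <- rbind(pts, polish_x(comp, M, j))
    for (i in seq_len(n_grid)) pts <- rbind(pts, polish_y(comp, M, i))
    if (is.null(pts)) data.frame(x = numeric(), y = numeric())
    else data.frame(x = pts[, 1L], y = pts[, 2L])
  }
  nc1 <- nullcline(1L, U)
  nc2 <- nullcline(2L, V)

  # candidate cells: both components change sign among the 4 corners
  starts <- list()
  for (i in seq_len(n_grid - 1L)) for (j in seq_len(n_grid - 1L)) {
    cu <- c(U[i, j], U[i + 1L, j], U[i, j + 1L], U[i + 1L, j + 1L])
    cv <- c(V[i, j], V[i + 1L, j], V[i, j + 1L], V[i + 1L, j + 1L])
    if (min(cu) <= 0 && max(cu) >= 0 && min(cv) <= 0 && max(cv) >= 0)
      starts[[length(starts) + 1L]] <-
        c((xs[i] + xs[i + 1L]) / 2, (ys[j] + ys[j + 1L]) / 2)
  }
  # coarse lattice of extra starts (robustness when nullclines graze cells)
  for (x0 in seq(xlim[1L], xlim[2L], length.out = 7L))
    for (y0 in seq(ylim[1L], ylim[2L], length.out = 7L))
      starts[[length(starts) + 1L]] <- c(x0, y0)

  span <- max(xlim[2L] - xlim[1L], ylim[2L] - ylim[1L])
  fps <- list()
  for (s in starts) {
    r <- newton_solve(f, s, tol = min(tol, 1e-10))
    if (!r$converged) next
    x <- r$x
    if (x[1L] < xlim[1L] - 1e-9 || x[1L] > xlim[2L] + 1e-9 ||
        x[2L] < ylim[1L] - 1e-9 || x[2L] > ylim[2L] + 1e-9) next
    if (max(abs(f(x))) > tol) next
    dup <- any(vapply(fps, function(q)
      sqrt(sum((q$x - x)^2)) < 1e-6 * span, logical(1)))
    if (!dup) {
      lin <- linearize(f, x, margin)
      fps[[length(fps) + 1L]] <- list(x = x,
                                      eigenvalues = lin$eigenvalues,
                                      jacobian = lin$jacobian,
                                      label = lin$label,
                                      residual = max(abs(f(x))))
    }
  }
  o <- order(vapply(fps, function(q) q$x[1L], numeric(1)),
             vapply(fps, function(q) q$x[2L], numeric(1)))
  structure(list(grid = list(x = xs, y = ys),
                 vector_field = list(dx = U, dy = V),
                 nullclines = list(nc1, nc2),
                 fixed_points = fps[o]),
            class = "phase_plane")
}

#' @export
print.phase_plane <- function(x, ...) {
  cat("<phase_plane>", length(x$fixed_points), "fixed point(s)\n")
  for (fp in x$fixed_points)
    cat(sprintf("  (%.6g, %.6g)  %s  max Re(lambda) = %.4g\n",
                fp$x[1L], fp$x[2L], fp$label, max(Re(fp$eigenvalues))))
  invisible(x)
}

#' Grid-based bifurcation scan (codimension 1 or 2)
#'
#' For every point of a 1- or 2-axis parameter grid, locates fixed points by
#' state-space multi-start Newton iteration and labels their stability; for
#' codimension 1, reports the parameter intervals over which the linked
#' branch changes stability (at grid resolution).
#'
#' @param make_f `function(<param>, ...)` returning the vector field closure
#'   `function(y)` for the given parameter value(s); called with named
#'   arguments matching `names(grid)`.
#' @param grid named list of 1 or 2 numeric parameter vectors.
#' @param state_box list of `c(lo, hi)` ranges, one per state dimension.
#' @param n_starts starts per state axis for the multi-start search.
#' @param tol fixed-point acceptance tolerance.
#' @param margin stability margin.
#' @return object of class `"bifurcation_result"`: `points` (data.frame of
#'   parameter values, state coordinates, `max_re`, `label`) and, for one
#'   parameter, `change_points` (data.frame with bracket columns `lo`, `hi`).
#' @export
bifurcation_scan <- function(make_f, grid, state_box, n_starts = 7L,
                             tol = 1e-8, margin = 1e-3) {
  stopifnot(length(grid) %in% 1:2, !is.null(names(grid)))
  dim_s <- length(state_box)
  axes <- lapply(state_box, function(r) seq(r[1L], r[2L],
                                            length.out = n_starts))
  starts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))

  find_fps <- function(f) {
    fps <- list()
    span <- max(vapply(state_box, diff, numeric(1)))
    for (i in seq_len(nrow(starts))) {
      r <- newton_solve(f, starts[i, ], tol = min(tol, 1e-10))
      if (!r$converged) next
      x <- r$x
      inbox <- all(vapply(seq_len(dim_s), function(d)
        x[d] >= state_box[[d]][1L] - 1e-6 &&
        x[d] <= state_box[[d]][2L] + 1e-6, logical(1)))
      if (!inbox || max(abs(f(x))) > tol) next
      if (!any(vapply(fps, function(q)
        sqrt(sum((q$x - x)^2)) < 1e-6 * span, logical(1)))) {
        lin <- linearize(f, x, margin)
        fps[[length(fps) + 1L]] <- list(x = x,
                                        max_re = max(Re(lin$eigenvalues)),
                                        label = lin$label)
      }
    }
    fps
  }

  pgrid <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  per_point <- vector("list", nrow(pgrid))
  for (g in seq_len(nrow(pgrid))) {
    f <- do.call(make_f, as.list(pgrid[g, , drop = FALSE]))
    fps <- find_fps(f)
    per_point[[g]] <- fps
    for (fp in fps) {
      rec <- c(as.list(pgrid[g, , drop = FALSE]),
               as.list(stats::setNames(fp$x,
                                       paste0("s", seq_along(fp$x)))),
               list(max_re = fp$max_re, label = fp$label))
      rows[[length(rows) + 1L]] <- rec
    }
  }
  points <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  change_points <- NULL
  if (length(grid) == 1L) {
    pv <- grid[[1L]]
    ch <- NULL
    for (g in seq_len(length(pv) - 1L)) {
      a <- per_point[[g]]
      b <- per_point[[g + 1L]]
      if (!length(a) || !length(b)) next
      for (fp in a) {
        # link to the nearest branch point at the next parameter value
        dists <- vapply(b, function(q) sqrt(sum((q$x - fp$x)^2)),
                        numeric(1))
        nb <- b[[which.min(dists)]]
        if (sign(fp$max_re) != sign(nb$max_re))
          ch <- rbind(ch, data.frame(lo = pv[g], hi = pv[g + 1L],
                                     from = fp$label, to = nb$label))
      }
    }
    change_points <- if (is.null(ch))
      data.frame(lo = numeric(), hi = numeric(),
                 from = character(), to = character()) else ch
  }
  structure(list(points = points, change_points = change_points,
                 grid = grid),
            class = "bifurcation_result")
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat("<bifurcation_result>", nrow(x$points), "branch points over",
      paste(names(x$grid), collapse = " x "), "\n")
  if (!is.null(x$change_points) && nrow(x$change_points))
    for (i in seq_len(nrow(x$change_points)))
      cat(sprintf("  stability change in (%g, %g): %s -> %s\n",
                  x$change_points$lo[i], x$change_points$hi[i],
                  x$change_points$from[i], x$change_points$to[i]))
  invisible(x)
}

#' Find fixed/slow points of a high-dimensional system
#'
#' Minimizes `q(x) = 0.5*||F(x)||^2` from each seed, keeps minima with
#' `||F||_inf <= tol`, merges points closer than `dedupe_radius` keeping the
#' lowest `q`, and linearizes around each survivor. The default optimizer is
#' Levenberg-Marquardt nonlinear least squares; `optimizer = "gd"` selects
#' plain gradient descent with backtracking line search.
#'
#' @param F vector field (or discrete-map displacement `x[t+1] - x[t]`).
#' @param seeds numeric matrix of candidate starts (one per row), e.g.
#'   states sampled from a simulated trajectory, or random states.
#' @param tol acceptance tolerance on `||F(x)||_inf` (default 1e-6).
#' @param dedupe_radius merge radius; default `0.01 * sqrt(dim)`.
#' @param optimizer `"lm"` or `"gd"`.
#' @param max_iter optimizer iteration cap.
#' @param step initial gradient-descent step size.
#' @param margin stability margin for labels.
#' @return object of class `"slow_points"`: list of points with `x`, `q`,
#'   `residual`, `eigenvalues`, `label`, sorted by `q`; plus `diagnostic`
#'   when empty.
#' @export
find_slow_points <- function(F, seeds, tol = 1e-6, dedupe_radius = NULL,
                             optimizer = c("lm", "gd"), max_iter = 200L,
                             step = 0.1, margin = 1e-3) {
  optimizer <- match.arg(optimizer)
  seeds <- as.matrix(seeds)
  if (any(!is.finite(seeds))) stop("seeds must be finite", call. = FALSE)
  dim_s <- ncol(seeds)
  if (is.null(dedupe_radius)) dedupe_radius <- 0.01 * sqrt(dim_s)

  minimize <- function(x0) {
    if (optimizer == "lm") {
      r <- tryCatch(minpack.lm::nls.lm(
        par = x0, fn = function(x) F(x),
        control = minpack.lm::nls.lm.control(
          maxiter = min(max_iter, 1000L), ftol = 1e-15, ptol = 1e-15,
          gtol = 0)),
        error = function(e) NULL)
      if (is.null(r)) return(NULL)
      as.numeric(r$par)
    } else {
      x <- x0
      s <- step
      for (it in seq_len(max_iter)) {
        Fx <- F(x)
        q0 <- 0.5 * sum(Fx^2)
        if (max(abs(Fx)) <= tol) break
        g <- as.numeric(crossprod(numeric_jacobian(F, x), Fx))
        gn <- sqrt(sum(g^2))
        if (gn == 0) break
        # backtracking line search on q
        s_try <- s
        repeat {
          xn <- x - s_try * g
          Fn <- F(xn)
          if (all(is.finite(Fn)) && 0.5 * sum(Fn^2) < q0) break
          s_try <- s_try / 2
          if (s_try < 1e-14) break
        }
        if (s_try < 1e-14) break
        x <- x - s_try * g
        s <- s_try * 2
      }
      x
    }
  }

  cands <- list()
  for (i in seq_len(nrow(seeds))) {
    x <- minimize(seeds[i, ])
    if (is.null(x) || any(!is.finite(x))) next
    Fx <- F(x)
    if (max(abs(Fx)) <= tol)
      cands[[length(cands) + 1L]] <- list(x = x, q = 0.5 * sum(Fx^2),
                                          residual = max(abs(Fx)))
  }
  if (!length(cands))
    return(structure(list(points = list(),
                          diagnostic = "no seed converged below tol"),
                     class = "slow_points"))
  # dedupe: lowest q wins; ordering independent of seed order
  o <- order(vapply(cands, `[[`, numeric(1), "q"))
  cands <- cands[o]
  kept <- list()
  for (cd in cands) {
    if (!any(vapply(kept, function(k)
      sqrt(sum((k$x - cd$x)^2)) < dedupe_radius, logical(1))))
      kept[[length(kept) + 1L]] <- cd
  }
  pts <- lapply(kept, function(k) {
    lin <- linearize(F, k$x, margin)
    c(k, list(eigenvalues = lin$eigenvalues, label = lin$label))
  })
  structure(list(points = pts, diagnostic = NULL), class = "slow_points")
}

#' @export
print.slow_points <- function(x, ...) {
  cat("<slow_points>", length(x$points), "accepted point(s)\n")
  for (p in head(x$points, 10L))
    cat(sprintf("  q = %.3g  ||F||inf = %.3g  %s\n", p$q, p$residual,
                p$label))
  if (length(x$points) > 10L) cat("  ...\n")
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' Tabulate analyzer results
#'
#' @param x a `"slow_points"` or `"phase_plane"` object.
#' @return data.frame with one row per fixed point (state coordinates,
#'   residual, max real eigenvalue part, label).
#' @export
fixed_point_table <- function(x) {
  pts <- if (inherits(x, "slow_points")) x$points else x$fixed_points
  if (!length(pts))
    return(data.frame())
  do.call(rbind, lapply(pts, function(p) {
    d <- as.data.frame(as.list(stats::setNames(
      p$x, paste0("s", seq_along(p$x)))))
    d$residual <- if (!is.null(p$residual)) p$residual else NA_real_
    d$max_re <- max(Re(p$eigenvalues))
    d$label <- p$label
    d
  }))
}
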