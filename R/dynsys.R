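# Core abstraction: a dynamical model is a tree of nodes, each owning named
# state vectors and an update rule; composites delegate to children first and
# then integrate their own states (single-step causal pipeline).

#' Create a dynamical-system node
#'
#' A node is the unit of model composition: it owns named parameters, named
#' numeric state vectors, and an update rule advancing those states by one
#' time step. Nodes compose into trees with [compose()]; the full state of a
#' composite is the disjoint union of its own states and all descendants'
#' states, addressed by dotted paths (e.g. `"INa.m"`).
#'
#' @param name identifier (must not contain `"."`, reserved for paths).
#' @param params named list of constants.
#' @param states named list of numeric vectors (initial values). Shapes are
#'   fixed after creation.
#' @param update `function(node, t, dt, inp)` advancing `node$states` in
#'   place, or `NULL` for a pure container. `inp` is the named list of
#'   external input values for the current step.
#' @param reset optional `function(node)` restoring initial state; by default
#'   the initial state snapshot is restored.
#' @return an environment of class `"dyn_node"`.
#' @export
dyn_node <- function(name, params = list(), states = list(), update = NULL,
                     reset = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string", call. = FALSE)
  if (grepl(".", name, fixed = TRUE))
    stop("node name must not contain '.': ", name, call. = FALSE)
  stopifnot(is.list(params), is.list(states))
  if (length(states) && is.null(names(states)))
    stop("states must be named", call. = FALSE)
  node <- new.env(parent = emptyenv())
  node$name <- name
  node$params <- params
  node$states <- lapply(states, function(x) as.numeric(x))
  names(node$states) <- names(states)
  node$init_states <- node$states
  node$children <- list()
  node$parent <- NULL
  node$own_update <- update
  node$own_reset <- reset
  class(node) <- "dyn_node"
  node
}

#' @export
print.dyn_node <- function(x, ...) {
  cat("<dyn_node>", x$name, "\n")
  cat("  states:  ", paste(names(x$states), collapse = ", "), "\n")
  cat("  children:", if (length(x$children)) paste(names(x$children), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

is_ancestor <- function(a, b) {
  # is `a` an ancestor of (or identical to) `b`?
  p <- b
  while (!is.null(p)) {
    if (identical(p, a)) return(TRUE)
    p <- p$parent
  }
  FALSE
}

#' Compose a child node into a parent
#'
#' Children update in insertion order, before the parent's own update rule
#' runs; the parent's state listing includes child states under the prefixed
#' dotted path.
#'
#' @param parent,child `dyn_node` objects.
#' @param name child name within the parent; defaults to `child$name`.
#' @return the parent, invisibly (modified in place).
#' @export
compose <- function(parent, child, name = child$name) {
  stopifnot(inherits(parent, "dyn_node"), inherits(child, "dyn_node"))
  if (grepl(".", name, fixed = TRUE))
    stop("child name must not contain '.': ", name, call. = FALSE)
  if (name %in% names(parent$children))
    stop("duplicate child name: ", name, call. = FALSE)
  if (is_ancestor(child, parent))
    stop("composition would create a cycle: ", name, call. = FALSE)
  child$parent <- parent
  parent$children[[name]] <- child
  invisible(parent)
}

#' List all state paths of a node tree
#'
#' @param node a `dyn_node`.
#' @return character vector of dotted paths, own states first, then children
#'   in insertion order.
#' @export
state_paths <- function(node) {
  own <- names(node$states)
  if (is.null(own)) own <- character()
  kid <- unlist(lapply(names(node$children), function(nm) {
    paste(nm, state_paths(node$children[[nm]]), sep = ".")
  }))
  c(own, kid)
}

#' Resolve a dotted state path to (node, state name)
#' @noRd
resolve_state <- function(node, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  cur <- node
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (i == length(parts) && p %in% names(cur$states))
      return(list(node = cur, var = p))
    if (p %in% names(cur$children)) {
      cur <- cur$children[[p]]
    } else {
      stop("cannot resolve state path '", path, "' at '", p, "'",
           call. = FALSE)
    }
  }
  stop("path '", path, "' names a node, not a state", call. = FALSE)
}

#' Read a state value by dotted path
#' @param node a `dyn_node`.
#' @param path dotted path such as `"pop.V"`.
#' @export
get_state <- function(node, path) {
  r <- resolve_state(node, path)
  r$node$states[[r$var]]
}

#' Set a state value by dotted path (shape must be preserved)
#' @inheritParams get_state
#' @param value numeric replacement of identical length.
#' @export
set_state <- function(node, path, value) {
  r <- resolve_state(node, path)
  if (length(value) != length(r$node$states[[r$var]]))
    stop("state shape is fixed after initialization: ", path, call. = FALSE)
  r$node$states[[r$var]] <- as.numeric(value)
  invisible(node)
}

#' Advance a node tree by one step (children first, insertion order)
#' @param node a `dyn_node`.
#' @param t current time (ms), `dt` step (ms), `inp` named input list.
#' @param dt step in ms.
#' @param inp named list of external inputs for this step.
#' @export
step_node <- function(node, t, dt, inp = list()) {
  for (ch in node$children) step_node(ch, t, dt, inp)
  if (!is.null(node$own_update)) node$own_update(node, t, dt, inp)
  invisible(node)
}

#' Restore a node tree to its initial state
#' @param node a `dyn_node`.
#' @export
reset_node <- function(node) {
  for (ch in node$children) reset_node(ch)
  if (!is.null(node$own_reset)) node$own_reset(node)
  else node$states <- node$init_states
  invisible(node)
}

collect_state_refs <- function(node, prefix = NULL) {
  out <- list()
  for (v in names(node$states)) {
    p <- if (is.null(prefix)) v else paste(prefix, v, sep = ".")
    out[[p]] <- list(node = node, var = v)
  }
  for (nm in names(node$children)) {
    p <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    out <- c(out, collect_state_refs(node$children[[nm]], p))
  }
  out
}

#' Simulate a model and record monitored variables
#'
#' Runs `ceiling(duration/dt)` steps. All randomness inside model updates is
#' driven by R's RNG, seeded once at entry, so identical
#' `(model, inputs, seed)` produce bit-identical records. On the first
#' non-finite state the run aborts with a diagnostic naming the step and the
#' offending variable.
#'
#' @param model a `dyn_node` (it is reset before the run).
#' @param duration total simulated time, ms (> 0).
#' @param dt step, ms (> 0).
#' @param inputs named list; each element is a scalar, a length-`n_steps`
#'   numeric vector (value per step), a matrix with `n_steps` rows, or a
#'   `function(t, step)` returning the current value.
#' @param monitors character vector of dotted state paths to record.
#' @param seed integer RNG seed.
#' @param record_every positive integer sampling stride applied to all
#'   monitors; recorded length is `floor(n_steps / record_every)`.
#' @return a `simulation_record`: list with `times` (ms), `series` (named
#'   list; a matrix of samples x variable-length per monitor) and `meta`.
#' @export
run_simulation <- function(model, duration, dt, inputs = list(),
                           monitors = character(), seed = 1L,
                           record_every = 1L) {
  stopifnot(inherits(model, "dyn_node"))
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be > 0", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  record_every <- as.integer(record_every)
  stopifnot(record_every >= 1L)
  n_steps <- as.integer(ceiling(duration / dt - 1e-9))

  reset_node(model)
  set.seed(as.integer(seed))

  refs <- collect_state_refs(model)
  mon_refs <- lapply(monitors, function(p) {
    if (is.null(refs[[p]]))
      stop("monitor path does not resolve: '", p, "'", call. = FALSE)
    refs[[p]]
  })
  names(mon_refs) <- monitors

  n_rec <- n_steps %/% record_every
  series <- lapply(mon_refs, function(r)
    matrix(NA_real_, n_rec, length(r$node$states[[r$var]])))
  times <- numeric(n_rec)

  input_at <- function(x, t, k) {
    if (is.function(x)) x(t, k)
    else if (is.matrix(x)) x[k, ]
    else if (length(x) > 1L) x[[k]]
    else x
  }

  ri <- 0L
  for (k in seq_len(n_steps)) {
    t <- (k - 1L) * dt
    inp <- lapply(inputs, input_at, t = t, k = k)
    step_node(model, t, dt, inp)
    for (r in refs) {
      v <- r$node$states[[r$var]]
      if (anyNA(v) || !all(is.finite(v)))
        stop(sprintf("divergence: non-finite state '%s' in node '%s' at step %d (t = %g ms)",
                     r$var, r$node$name, k, t), call. = FALSE)
    }
    if (k %% record_every == 0L) {
      ri <- ri + 1L
      times[ri] <- k * dt
      for (m in seq_along(mon_refs)) {
        r <- mon_refs[[m]]
        series[[m]][ri, ] <- r$node$states[[r$var]]
      }
    }
  }

  structure(list(
    times = times,
    series = series,
    meta = list(model = model$name, duration = duration, dt = dt,
                seed = as.integer(seed), record_every = record_every,
                n_steps = n_steps)
  ), class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  cat("<simulation_record>", x$meta$model, "\n")
  cat(sprintf("  %d steps, dt = %g ms, duration = %g ms, seed = %d\n",
              x$meta$n_steps, x$meta$dt, x$meta$duration, x$meta$seed))
  cat("  monitors:", paste(names(x$series), collapse = ", "), "\n")
  invisible(x)
}

#' Run a model factory over a parameter grid
#'
#' @param factory `function(...)` returning a fresh `dyn_node` given one
#'   parameter combination (passed as named arguments).
#' @param param_grid named list of parameter vectors/lists.
#' @param mode `"cartesian"` (full crossing, varying the first name fastest)
#'   or `"zip"` (parallel iteration; all lengths must match).
#' @param ... forwarded to [run_simulation()] (duration, dt, monitors, seed,
#'   inputs may be a function of the grid row via `inputs_fn`).
#' @param inputs_fn optional `function(...)` of the grid row returning the
#'   `inputs` list for that run.
#' @return list of `simulation_record`s in grid order.
#' @export
batch_run <- function(factory, param_grid, mode = c("cartesian", "zip"),
                      ..., inputs_fn = NULL) {
  mode <- match.arg(mode)
  if (length(param_grid) == 0L) return(list())
  if (mode == "zip") {
    lens <- lengths(param_grid)
    if (length(unique(lens)) != 1L)
      stop("zipped grid lengths mismatch: ",
           paste(lens, collapse = ", "), call. = FALSE)
    rows <- lapply(seq_len(lens[[1L]]), function(i)
      lapply(param_grid, `[[`, i))
  } else {
    idx <- expand.grid(lapply(param_grid, seq_along), KEEP.OUT.ATTRS = FALSE)
    if (nrow(idx) == 0L) return(list())
    rows <- lapply(seq_len(nrow(idx)), function(i)
      lapply(seq_along(param_grid), function(j)
        param_grid[[j]][[idx[i, j]]]))
    rows <- lapply(rows, function(r) { names(r) <- names(param_grid); r })
  }
  lapply(rows, function(r) {
    names(r) <- names(param_grid)
    model <- do.call(factory, r)
    extra <- list(...)
    if (!is.null(inputs_fn)) extra$inputs <- do.call(inputs_fn, r)
    do.call(run_simulation, c(list(model = model), extra))
  })
}

# ---- delay buffers ---------------------------------------------------------

#' Ring buffer for delayed state access
#'
#' Holds `round(max_delay/dt)` past values; delays are rounded to the nearest
#' integer step (no interpolation). Before history fills, reads return the
#' declared initial value.
#'
#' @param max_delay maximum readable delay, ms.
#' @param dt step, ms.
#' @param init initial value (scalar or vector); also the pre-history value.
#' @return environment of class `"delay_buffer"`.
#' @export
delay_buffer <- function(max_delay, dt, init = 0) {
  stopifnot(max_delay >= 0, dt > 0)
  n <- as.integer(round(max_delay / dt))
  buf <- new.env(parent = emptyenv())
  buf$dt <- dt
  buf$max_steps <- n
  buf$len <- length(init)
  buf$hist <- matrix(as.numeric(init), n + 1L, length(init), byrow = TRUE)
  buf$pos <- 1L   # row holding the current value
  class(buf) <- "delay_buffer"
  buf
}

#' Push the current value into a delay buffer
#' @param buf a `delay_buffer`; `value` the new current value.
#' @param value numeric of the buffer's width.
#' @export
delay_push <- function(buf, value) {
  stopifnot(inherits(buf, "delay_buffer"), length(value) == buf$len)
  buf$pos <- if (buf$pos == nrow(buf$hist)) 1L else buf$pos + 1L
  buf$hist[buf$pos, ] <- value
  invisible(buf)
}

#' Read a delayed value
#' @param buf a `delay_buffer`.
#' @param d delay in ms, `0 <= d <= max_delay`; rounded to the nearest step.
#' @return the value stored `round(d/dt)` pushes ago.
#' @export
delay_read <- function(buf, d) {
  stopifnot(inherits(buf, "delay_buffer"))
  k <- as.integer(round(d / buf$dt))
  if (d < 0 || k > buf$max_steps)
    stop("delay ", d, " ms outside buffer capacity (",
         buf$max_steps * buf$dt, " ms)", call. = FALSE)
  i <- buf$pos - k
  if (i < 1L) i <- i + nrow(buf$hist)
  v <- buf$hist[i, ]
  if (buf$len == 1L) v[[1L]] else v
}
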