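# Run configuration and command-line entry points. Configs are YAML or JSON
# (chosen by extension); every run emits a metadata file that is itself a
# valid config reproducing the run bit-identically.

#' Read a run configuration (YAML or JSON)
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: .", ext, call. = FALSE))
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  cfg
}

#' Write a configuration as JSON
#' @param cfg named list; `path` destination.
#' @param path destination file.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

zoo_model_registry <- list(
  lif = function(params) do.call(lif_neuron, params),
  hh = function(params) do.call(hh_neuron, params),
  coba = function(params) do.call(build_coba, params),
  cann = function(params) do.call(cann_network, params),
  fhn = function(params) do.call(fhn_neuron, params)
)

vector_field_registry <- list(
  fhn = function(params) do.call(fhn_vector_field, params),
  wc = function(params) do.call(wc_vector_field, params),
  decision = function(params) do.call(decision_vector_field, params)
)

build_model_from_config <- function(spec) {
  if (is.null(spec$name) || !spec$name %in% names(zoo_model_registry))
    stop("unknown or missing model name: ", spec$name %||% "<none>",
         call. = FALSE)
  params <- spec$params %||% list()
  zoo_model_registry[[spec$name]](params)
}

build_inputs_from_config <- function(spec, dt) {
  if (is.null(spec)) return(list())
  out <- list()
  for (nm in names(spec)) {
    s <- spec[[nm]]
    out[[nm]] <- if (is.numeric(s)) {
      s
    } else if (identical(s$kind, "section")) {
      section_input(unlist(s$values), unlist(s$durations), dt)
    } else if (identical(s$kind, "constant")) {
      s$value
    } else stop("unknown input kind for '", nm, "'", call. = FALSE)
  }
  out
}

#' Flatten a simulation record to a data frame
#'
#' One time column plus one column per monitored scalar; array monitors are
#' flattened with 0-based index-suffixed headers (`V_0`, `V_1`, ...).
#'
#' @param record a `simulation_record`.
#' @return data.frame.
#' @export
record_to_frame <- function(record) {
  df <- data.frame(time_ms = record$times)
  for (nm in names(record$series)) {
    M <- record$series[[nm]]
    if (ncol(M) == 1L) df[[nm]] <- M[, 1L]
    else for (j in seq_len(ncol(M)))
      df[[paste0(nm, "_", j - 1L)]] <- M[, j]
  }
  df
}

#' Write a simulation record to a directory
#'
#' Emits `record.csv` (monitor series), `spikes.csv` (two-column event
#' table, when a `spike` monitor is present), and `metadata.json` — a full
#' config that re-executes the run bit-identically.
#'
#' @param record a `simulation_record`.
#' @param dir output directory (created if needed).
#' @param config the resolved run config to embed in the metadata.
#' @return invisible character vector of written paths.
#' @export
write_record <- function(record, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, "record.csv")
  utils::write.csv(record_to_frame(record), p, row.names = FALSE)
  paths <- c(paths, p)
  spk <- grep("(^|\\.)spike$", names(record$series), value = TRUE)
  if (length(spk)) {
    ev <- spikes_to_events(record$series[[spk[1L]]] > 0,
                           record$meta$dt * record$meta$record_every)
    p <- file.path(dir, "spikes.csv")
    utils::write.csv(ev, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- c(config %||% list(),
            list(meta = record$meta,
                 versions = list(
                   package = as.character(utils::packageVersion("neurodyn")),
                   r = paste(R.version$major, R.version$minor, sep = "."))))
  p <- file.path(dir, "metadata.json")
  write_config(meta, p)
  paths <- c(paths, p)
  invisible(paths)
}

cli_guard <- function(expr, verbose = TRUE) {
  res <- tryCatch(list(code = 0L, value = force(expr)),
    error = function(e) {
      msg <- conditionMessage(e)
      code <- if (grepl("divergence", msg)) 3L else 2L
      if (verbose) message("error: ", msg)
      list(code = code, value = NULL)
    })
  res
}

#' Run a simulation from a config file
#'
#' Config sections: `model` (`name` from the zoo registry + `params`),
#' `run` (`duration`, `dt`, `seed`, optional `record_every`, `monitors`,
#' `inputs`), optional `output.dir`. Writes monitor CSVs, a spike-event CSV
#' and a `metadata.json` that reproduces the run.
#'
#' @param config path to a YAML/JSON config, or an equivalent named list.
#' @param outdir output directory override.
#' @param quiet suppress messages.
#' @return invisible exit code: 0 success, 2 invalid config, 3 divergence.
#' @export
cli_simulate <- function(config, outdir = NULL, quiet = FALSE) {
  r <- cli_guard({
    cfg <- if (is.character(config)) read_config(config) else config
    if (is.null(cfg$model) || is.null(cfg$run))
      stop("config must contain 'model' and 'run' sections", call. = FALSE)
    run <- cfg$run
    if (is.null(run$duration) || is.null(run$dt) || is.null(run$seed))
      stop("run section needs duration, dt, seed", call. = FALSE)
    model <- build_model_from_config(cfg$model)
    inputs <- build_inputs_from_config(run$inputs, run$dt)
    rec <- run_simulation(
      model, duration = run$duration, dt = run$dt, inputs = inputs,
      monitors = unlist(run$monitors) %||% character(),
      seed = run$seed, record_every = run$record_every %||% 1L)
    dir <- outdir %||% cfg$output$dir %||% stop("no output directory given",
                                               call. = FALSE)
    write_record(rec, dir, config = cfg[c("model", "run")])
    if (!quiet) message("simulate: wrote ", dir)
    rec
  }, verbose = !quiet)
  invisible(r$code)
}

#' Train a reservoir readout from a config file
#'
#' Config: `train` section with `method` (`ridge`/`force`), `reservoir`
#' (arguments of [reservoir_params()]), optional `lambda`, `alpha`,
#' `duration`, `dt`; optional `output.dir`. Writes `weights.csv` and
#' `report.json` (with the test MSE).
#'
#' @inheritParams cli_simulate
#' @return invisible exit code (0/2/3).
#' @export
cli_train <- function(config, outdir = NULL, quiet = FALSE) {
  r <- cli_guard({
    cfg <- if (is.character(config)) read_config(config) else config
    tr <- cfg$train
    if (is.null(tr)) stop("config must contain a 'train' section",
                          call. = FALSE)
    rp <- do.call(reservoir_params, tr$reservoir %||% list())
    fit <- train_and_forecast(
      task = tr$task %||% "lorenz_prediction",
      method = tr$method %||% "ridge", params = rp,
      lambda = tr$lambda %||% 1e-6, alpha = tr$alpha %||% 1,
      duration = tr$duration %||% 60, dt = tr$dt %||% 0.01)
    dir <- outdir %||% cfg$output$dir %||% stop("no output directory given",
                                               call. = FALSE)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(fit$weights),
                     file.path(dir, "weights.csv"), row.names = FALSE)
    write_config(list(train = tr, mse = fit$mse,
                      train_mse = fit$train_mse, meta = fit$meta),
                 file.path(dir, "report.json"))
    if (!quiet) message("train: test MSE = ", signif(fit$mse, 6))
    fit
  }, verbose = !quiet)
  invisible(r$code)
}

#' Run a dynamics analysis from a config file
#'
#' Config: `analysis` section with `kind` (`phase_plane`, `bifurcation`,
#' `slow_points`), a `model` (vector-field registry name: `fhn`, `wc`,
#' `decision` + `params`), and kind-specific settings. Writes
#' `fixed_points.csv` and `summary.json`.
#'
#' @inheritParams cli_simulate
#' @return invisible exit code (0/2/3).
#' @export
cli_analyze <- function(config, outdir = NULL, quiet = FALSE) {
  r <- cli_guard({
    cfg <- if (is.character(config)) read_config(config) else config
    an <- cfg$analysis
    if (is.null(an)) stop("config must contain an 'analysis' section",
                          call. = FALSE)
    dir <- outdir %||% cfg$output$dir %||% stop("no output directory given",
                                               call. = FALSE)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (identical(an$kind, "phase_plane")) {
      vf <- vector_field_registry[[an$model$name %||% ""]]
      if (is.null(vf)) stop("unknown vector field: ", an$model$name,
                            call. = FALSE)
      f <- vf(an$model$params %||% list())
      pp <- phase_plane_2d(f, unlist(an$xlim), unlist(an$ylim),
                           n_grid = an$n_grid %||% 50L,
                           tol = an$tol %||% 1e-8)
      tab <- fixed_point_table(pp)
      utils::write.csv(tab, file.path(dir, "fixed_points.csv"),
                       row.names = FALSE)
      write_config(list(analysis = an, n_fixed_points = nrow(tab)),
                   file.path(dir, "summary.json"))
      pp
    } else if (identical(an$kind, "bifurcation")) {
      vf <- vector_field_registry[[an$model$name %||% ""]]
      if (is.null(vf)) stop("unknown vector field: ", an$model$name,
                            call. = FALSE)
      base <- an$model$params %||% list()
      grid <- lapply(an$grid, function(g)
        seq(g$from, g$to, by = g$by))
      names(grid) <- names(an$grid)
      make_f <- function(...) {
        pp <- utils::modifyList(base, list(...))
        vf(pp)
      }
      br <- bifurcation_scan(make_f, grid,
                             state_box = lapply(an$state_box, unlist),
                             tol = an$tol %||% 1e-8)
      utils::write.csv(br$points, file.path(dir, "fixed_points.csv"),
                       row.names = FALSE)
      write_config(list(analysis = an,
                        n_change_points =
                          if (is.null(br$change_points)) NA
                          else nrow(br$change_points)),
                   file.path(dir, "summary.json"))
      br
    } else if (identical(an$kind, "slow_points")) {
      if (!identical(an$model$name, "cann"))
        stop("slow_points config supports the 'cann' model", call. = FALSE)
      net <- do.call(cann_network, an$model$params %||% list())
      seeds <- cann_slow_point_seeds(net, n_seeds = an$n_seeds %||% 16L)
      sp <- find_slow_points(function(u) cann_derivatives(net, u), seeds,
                             tol = an$tol %||% 1e-6)
      tab <- fixed_point_table(sp)
      utils::write.csv(tab, file.path(dir, "fixed_points.csv"),
                       row.names = FALSE)
      write_config(list(analysis = an, n_fixed_points = nrow(tab)),
                   file.path(dir, "summary.json"))
      sp
    } else stop("unknown analysis kind: ", an$kind, call. = FALSE)
  }, verbose = !quiet)
  invisible(r$code)
}

#' Emit named synthetic fixtures with a manifest
#'
#' @param names character vector among `"lorenz"`, `"random_csr"`,
#'   `"linear_system"`.
#' @param outdir output directory.
#' @param seed integer seed.
#' @param quiet suppress messages.
#' @return invisible exit code.
#' @export
cli_fixtures <- function(names = c("lorenz", "random_csr"), outdir,
                         seed = 1L, quiet = FALSE) {
  r <- cli_guard({
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(seed = seed, files = list())
    for (nm in names) {
      if (nm == "lorenz") {
        ser <- lorenz_series(duration = 10, seed = seed)
        p <- file.path(outdir, "lorenz.csv")
        utils::write.csv(as.data.frame(ser), p, row.names = FALSE)
        manifest$files$lorenz <- basename(p)
      } else if (nm == "random_csr") {
        m <- random_csr(50, 40, 0.1, seed = seed)
        p <- file.path(outdir, "random_csr.mtx")
        csr_write_mtx(m, p)
        manifest$files$random_csr <- basename(p)
      } else if (nm == "linear_system") {
        ls <- random_linear_system(8, 0.9, seed = seed)
        p <- file.path(outdir, "linear_system.csv")
        utils::write.csv(cbind(as.data.frame(ls$A), b = ls$b), p,
                         row.names = FALSE)
        manifest$files$linear_system <- basename(p)
      } else stop("unknown fixture: ", nm, call. = FALSE)
    }
    write_config(manifest, file.path(outdir, "manifest.json"))
    manifest
  }, verbose = !quiet)
  invisible(r$code)
}

#' Trajectory-derived seeds for the CANN slow-point search
#'
#' Simulates one stimulated bump, removes the stimulus to let it settle,
#' and returns the settled profile rotated to `n_seeds` evenly spaced ring
#' positions (plus the origin state), the natural candidate set for a line
#' attractor.
#'
#' @param net a [cann_network()] node.
#' @param n_seeds number of rotated bump seeds.
#' @param settle_ms simulated settling time per phase.
#' @param dt integration step, ms.
#' @return matrix `[(n_seeds + 1) x n]` of seed states.
#' @export
cann_slow_point_seeds <- function(net, n_seeds = 16L, settle_ms = 20,
                                  dt = 0.05) {
  p <- net$params
  reset_node(net)
  stim <- cann_stimulus(net, center = 0)
  steps <- as.integer(settle_ms / dt)
  for (k in seq_len(steps)) step_node(net, (k - 1) * dt, dt,
                                      list(Iext = stim))
  for (k in seq_len(steps)) step_node(net, (k - 1) * dt, dt,
                                      list(Iext = 0))
  u0 <- net$states$u
  reset_node(net)
  shifts <- round(seq(0, p$n - 1, length.out = n_seeds + 1L))[seq_len(n_seeds)]
  seeds <- t(vapply(shifts, function(s)
    u0[((seq_len(p$n) - 1L - s) %% p$n) + 1L], numeric(p$n)))
  rbind(seeds, numeric(p$n))
}

#' Package selftest
#'
#' Runs a handful of fast internal consistency checks (operator oracle,
#' integrator sanity, record determinism) and reports failures.
#'
#' @param quiet suppress messages.
#' @return invisible exit code (0 on success).
#' @export
cli_selftest <- function(quiet = FALSE) {
  r <- cli_guard({
    m <- random_csr(20, 15, 0.2, seed = 7)
    v <- rnorm(20)
    stopifnot(max(abs(csr_matvec(m, v, TRUE) -
                      as.numeric(crossprod(csr_to_dense(m), v)))) < 1e-10)
    stopifnot(abs(ode_step(function(t, y) -y, 1, 0, 0.1, "euler") - 0.9) <
              1e-12)
    lif <- lif_neuron(tau = 10, V_th = 10, V_reset = 0, V_rest = 0)
    r1 <- run_simulation(lif, 10, 0.1, inputs = list(I = 12),
                         monitors = "V", seed = 3)
    r2 <- run_simulation(lif, 10, 0.1, inputs = list(I = 12),
                         monitors = "V", seed = 3)
    stopifnot(identical(r1$series, r2$series))
    if (!quiet) message("selftest: ok")
    TRUE
  }, verbose = !quiet)
  invisible(r$code)
}
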