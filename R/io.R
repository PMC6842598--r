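#' Save / load a trained model checkpoint
#'
#' Checkpoints are JSON text files holding every layer array, the activation
#' name, the library spec, coefficient values and mask, and the training
#' config echo. Numbers are written at full precision so a load reproduces
#' all arrays bitwise; \code{load_model} validates the format version and
#' required fields and names the missing field on error.
#'
#' @param model A \code{sindy_ae_model} (or a list with \code{params},
#'   \code{spec}, \code{xi}).
#' @param path Output file path.
#' @return \code{save_model} returns \code{path} invisibly;
#'   \code{load_model} returns the model.
#' @export
save_model <- function(model, path) {
  ser_stack <- function(st) lapply(st, function(l) {
    list(W = unclass(l$W), dim = dim(l$W), b = l$b)
  })
  obj <- list(
    format = "sindyae-checkpoint",
    version = 1L,
    package_version = as.character(utils::packageVersion("sindyae")),
    network = list(
      n = model$params$n, d = model$params$d,
      hidden_widths = model$params$hidden_widths,
      activation = model$params$activation, seed = model$params$seed,
      encoder = ser_stack(model$params$encoder),
      decoder = ser_stack(model$params$decoder)
    ),
    spec = unclass(model$spec),
    xi = list(values = as.vector(model$xi$values),
              mask = as.vector(model$xi$mask),
              dim = dim(model$xi$values),
              terms = rownames(model$xi$values)),
    config = if (!is.null(model$config)) serialize_config(model$config),
    validation_total = model$validation_total
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$weights <- unclass(cfg$weights)
  cfg$spec <- unclass(cfg$spec)
  cfg
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stop(sprintf(
                    "load_model: cannot parse '%s': %s", path,
                    conditionMessage(e)), call. = FALSE))
  for (field in c("format", "network", "spec", "xi")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("load_model: checkpoint missing field '%s'", field),
           call. = FALSE)
    }
  }
  if (!identical(obj$format, "sindyae-checkpoint")) {
    stop("load_model: not a sindyae checkpoint file", call. = FALSE)
  }
  de_stack <- function(st) lapply(st, function(l) {
    list(W = matrix(unlist(l$W), l$dim[1], l$dim[2]), b = as.numeric(l$b))
  })
  nw <- obj$network
  params <- structure(
    list(encoder = de_stack(nw$encoder), decoder = de_stack(nw$decoder),
         activation = nw$activation, n = as.integer(nw$n),
         d = as.integer(nw$d),
         hidden_widths = as.integer(nw$hidden_widths %||% integer(0)),
         seed = as.integer(nw$seed)),
    class = "sindy_ae_network")
  spec <- do.call(library_spec, obj$spec[c("latent_dim", "poly_order",
                                           "include_constant", "include_sine",
                                           "model_order")])
  xi <- coefficient_matrix(
    matrix(as.numeric(obj$xi$values), obj$xi$dim[1], obj$xi$dim[2]),
    matrix(as.numeric(obj$xi$mask), obj$xi$dim[1], obj$xi$dim[2]),
    terms = obj$xi$terms
  )
  structure(list(params = params, spec = spec, xi = xi,
                 config = obj$config,
                 validation_total = obj$validation_total),
            class = "sindy_ae_model")
}

#' Save / load a snapshot dataset
#'
#' JSON text container with named arrays \code{X}, \code{dX}, \code{ddX},
#' \code{times}, \code{traj_id} and a config echo, written at full precision.
#'
#' @param ds A \code{\link{snapshot_dataset}}.
#' @param path File path.
#' @return \code{save_dataset} returns \code{path} invisibly;
#'   \code{load_dataset} returns the dataset.
#' @export
save_dataset <- function(ds, path) {
  meta <- ds$metadata
  meta$V <- NULL  # auxiliary fields can be large; keep the config echo only
  meta$modes <- NULL
  obj <- list(
    format = "sindyae-dataset", version = 1L,
    package_version = as.character(utils::packageVersion("sindyae")),
    dim = dim(ds$X),
    X = as.vector(ds$X), dX = as.vector(ds$dX),
    ddX = if (!is.null(ds$ddX)) as.vector(ds$ddX),
    times = ds$times, traj_id = ds$traj_id, metadata = meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  for (field in c("format", "dim", "X", "dX")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("load_dataset: file missing field '%s'", field),
           call. = FALSE)
    }
  }
  m <- obj$dim[1]; n <- obj$dim[2]
  snapshot_dataset(
    matrix(as.numeric(obj$X), m, n), matrix(as.numeric(obj$dX), m, n),
    if (!is.null(obj$ddX)) matrix(as.numeric(obj$ddX), m, n),
    times = obj$times, traj_id = obj$traj_id,
    metadata = as.list(obj$metadata)
  )
}

#' Read an experiment configuration from YAML
#'
#' The file must contain a \code{benchmark} block (\code{name} plus generator
#' fields), a \code{training} block (fields of
#' \code{\link{training_config}}, with nested \code{weights} and
#' \code{spec}), and optional \code{n_instances}, \code{reference}
#' (\code{"lorenz"} or \code{"pendulum"}) and \code{seed} entries. Field
#' validation happens before any compute.
#'
#' @param path YAML file path.
#' @return A validated list of class \code{experiment_config}.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_experiment_config(cfg)
}

#' @rdname read_experiment_config
#' @param cfg A raw configuration list (as parsed from YAML).
#' @export
validate_experiment_config <- function(cfg) {
  for (field in c("benchmark", "training")) {
    if (is.null(cfg[[field]])) {
      stop(sprintf("experiment config missing required field '%s'", field),
           call. = FALSE)
    }
  }
  if (is.null(cfg$benchmark$name) ||
      !cfg$benchmark$name %in% c("lorenz", "rd", "pendulum", "linear_toy")) {
    stop("experiment config: benchmark$name must be one of lorenz, rd, pendulum, linear_toy",
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed %||% 0L)
  cfg$n_instances <- as.integer(cfg$n_instances %||% 1L)
  tr <- cfg$training
  spec_args <- tr$spec %||% list(latent_dim = 3)
  w_args <- tr$weights %||% list()
  tr$spec <- do.call(library_spec, spec_args)
  tr$weights <- do.call(loss_weights, w_args)
  tr$seed <- as.integer(tr$seed %||% cfg$seed)
  cfg$training <- do.call(training_config, tr)
  structure(cfg, class = "experiment_config")
}

build_benchmark_dataset <- function(bench, seed) {
  args <- bench
  args$name <- NULL
  args$seed <- as.integer(args$seed %||% seed)
  switch(
    bench$name,
    lorenz = generate_lorenz_dataset(do.call(lorenz_config, args)),
    rd = simulate_lambda_omega(do.call(lambda_omega_config, args)),
    pendulum = render_pendulum(do.call(pendulum_config, args)),
    linear_toy = do.call(generate_linear_toy, args)
  )
}

#' Run a full experiment from a configuration
#'
#' Orchestrates generate -> train_ensemble -> evaluate and writes every
#' artifact into \code{out_dir}: the config echo, per-instance checkpoints,
#' the best-model record, a coefficient table, the training history as
#' JSON-lines, and the evaluation report. A manifest records per-stage
#' status. Rerunning with the same config and seed reproduces the metrics.
#'
#' @param config An \code{experiment_config} (see
#'   \code{\link{read_experiment_config}}).
#' @param out_dir Output directory (created if missing).
#' @return The manifest list, invisibly; artifacts live in \code{out_dir}.
#' @export
run_experiment <- function(config, out_dir) {
  if (!inherits(config, "experiment_config")) {
    config <- validate_experiment_config(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list())
  stage <- function(name, fun) {
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    manifest$stages[[name]] <<- if (res$ok) "ok" else res$error
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    if (!res$ok) stop(sprintf("stage '%s' failed: %s", name, res$error),
                      call. = FALSE)
    res$value
  }
  yaml::write_yaml(list(benchmark = config$benchmark,
                        training = serialize_config(config$training),
                        n_instances = config$n_instances,
                        seed = config$seed,
                        package_version =
                          as.character(utils::packageVersion("sindyae"))),
                   file.path(out_dir, "config_echo.yaml"))
  ds <- stage("generate", function() {
    build_benchmark_dataset(config$benchmark, config$seed)
  })
  ens <- stage("train", function() {
    train_ensemble(ds, config$training, config$n_instances)
  })
  stage("save", function() {
    for (i in seq_along(ens$all)) {
      if (!inherits(ens$all[[i]], "error")) {
        save_model(ens$all[[i]],
                   file.path(out_dir, sprintf("instance_%02d.json", i)))
      }
    }
    save_model(ens$best, file.path(out_dir, "best_model.json"))
    write_coefficients(ens$best$xi, file.path(out_dir, "coefficients.csv"))
    hist_path <- file.path(out_dir, "history.jsonl")
    con <- file(hist_path, "w")
    on.exit(close(con))
    if (!is.null(ens$best$history)) {
      for (i in seq_len(nrow(ens$best$history))) {
        writeLines(jsonlite::toJSON(as.list(ens$best$history[i, ]),
                                    auto_unbox = TRUE, digits = NA), con)
      }
    }
    TRUE
  })
  report <- stage("evaluate", function() {
    rep <- evaluate_model(ens$best, ds)
    out <- unclass(rep)
    if (!is.null(config$reference)) {
      ref <- switch(config$reference,
                    lorenz = lorenz_reference(config$training$spec),
                    pendulum = pendulum_reference(config$training$spec))
      ms <- match_sparsity(ens$best$xi, ref, config$training$spec)
      out$identified <- ms$identified
      out$max_rel_dev <- ms$max_rel_dev
    }
    jsonlite::write_json(out, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    out
  })
  manifest$evaluation <- report
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Linear toy benchmark
#'
#' A fully linear system used for end-to-end validation: latent dynamics
#' \eqn{\dot z = A z} with a known stable matrix, lifted to \eqn{x = z V^T}
#' by a random orthonormal map, so the generating model (coordinates and
#' equations) is known by construction.
#'
#' @param n Ambient dimension.
#' @param d Latent dimension.
#' @param n_ics Number of trajectories.
#' @param t_span,dt Trajectory length and sampling interval.
#' @param A Latent dynamics matrix (default a damped rotation for d = 2).
#' @param seed RNG seed.
#' @return A \code{\link{snapshot_dataset}} whose metadata records \code{A}
#'   and the lifting map \code{V}.
#' @export
generate_linear_toy <- function(n = 4, d = 2, n_ics = 10, t_span = 10,
                                dt = 0.05, A = NULL, seed = 0L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  if (is.null(A)) {
    A <- if (d == 2) matrix(c(-0.5, -2, 2, -0.5), 2, 2) else
      diag(-seq(0.5, 1.5, length.out = d))
  }
  V <- qr.Q(qr(matrix(stats::rnorm(n * d), n, d)))
  times <- seq(0, t_span, by = dt)
  parts <- vector("list", n_ics)
  for (i in seq_len(n_ics)) {
    z0 <- stats::runif(d, -2, 2)
    deriv <- function(t, y, p) list(as.vector(A %*% y))
    sol <- deSolve::ode(z0, times, deriv, parms = NULL, rtol = 1e-10,
                        atol = 1e-12)
    z <- unname(sol[, -1, drop = FALSE])
    dz <- z %*% t(A)
    parts[[i]] <- list(X = z %*% t(V), dX = dz %*% t(V), times = times,
                       id = rep(i, length(times)))
  }
  snapshot_dataset(
    do.call(rbind, lapply(parts, `[[`, "X")),
    do.call(rbind, lapply(parts, `[[`, "dX")),
    times = unlist(lapply(parts, `[[`, "times")),
    traj_id = unlist(lapply(parts, `[[`, "id")),
    metadata = list(generator = "linear_toy", A = A, V = V, seed = seed)
  )
}
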