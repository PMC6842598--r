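#' Training configuration
#'
#' Bundles every knob of the joint autoencoder + sparse-dynamics optimization.
#' Values are package defaults chosen for the shipped benchmarks.
#'
#' @param epochs Number of training epochs.
#' @param batch_size Minibatch size (rows); batches at least as large as the
#'   training set mean full-batch gradient descent.
#' @param learning_rate Adam step size.
#' @param threshold Coefficient-magnitude cutoff \eqn{\tau} for sequential
#'   thresholding; 0 disables pruning.
#' @param threshold_interval Epochs between mask updates (>= 1).
#' @param refinement_epochs Extra epochs run after the main loop with the L1
#'   weight set to zero and the mask frozen, to polish surviving coefficients.
#' @param seed Integer seed controlling initialization and batching.
#' @param validation_fraction Fraction of trajectories (or rows) held out; in
#'   [0, 1).
#' @param weights A \code{\link{loss_weights}}.
#' @param spec A \code{\link{library_spec}}.
#' @param hidden_widths Encoder hidden-layer widths (decoder mirrored).
#' @param activation Activation name for \code{\link{init_network}}.
#' @param history_interval Record the train/validation loss breakdown every
#'   this many epochs (and always at the last epoch).
#' @return An object of class \code{training_config}.
#' @export
training_config <- function(epochs = 1000, batch_size = 1024,
                            learning_rate = 1e-3, threshold = 0.1,
                            threshold_interval = 500, refinement_epochs = 0,
                            seed = 0L, validation_fraction = 0.2,
                            weights = loss_weights(),
                            spec = library_spec(3),
                            hidden_widths = c(64, 32),
                            activation = "sigmoid",
                            history_interval = 1) {
  stopifnot(threshold_interval >= 1, validation_fraction >= 0,
            validation_fraction < 1, epochs >= 0, threshold >= 0)
  if (spec$model_order == 2 && !activation_funs(activation)$order2_ok) {
    stop(sprintf(
      "training_config: activation '%s' is not smooth enough for an order-2 model; use sigmoid or linear",
      activation), call. = FALSE)
  }
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, threshold = threshold,
    threshold_interval = as.integer(threshold_interval),
    refinement_epochs = as.integer(refinement_epochs), seed = as.integer(seed),
    validation_fraction = validation_fraction, weights = weights, spec = spec,
    hidden_widths = as.integer(hidden_widths), activation = activation,
    history_interval = as.integer(history_interval)
  ), class = "training_config")
}

#' Sequentially threshold a coefficient matrix
#'
#' Entries with magnitude below \code{tau} are zeroed and their mask bits
#' cleared. Already-masked entries never re-activate: pruning is one-way, so
#' repeated application is idempotent and the active set is non-increasing
#' over training.
#'
#' @param xi A \code{\link{coefficient_matrix}}.
#' @param tau Non-negative cutoff.
#' @return A new \code{coefficient_matrix}.
#' @export
apply_threshold <- function(xi, tau) {
  stopifnot(tau >= 0)
  mask <- xi$mask * (abs(xi$values) >= tau)
  coefficient_matrix(xi$values * mask, mask, terms = rownames(xi$values))
}

# ---- flat parameter list <-> structured params, for the Adam update ----

params_to_list <- function(params, xi) {
  out <- list()
  for (l in seq_along(params$encoder)) {
    out[[paste0("eW", l)]] <- params$encoder[[l]]$W
    out[[paste0("eb", l)]] <- params$encoder[[l]]$b
  }
  for (l in seq_along(params$decoder)) {
    out[[paste0("dW", l)]] <- params$decoder[[l]]$W
    out[[paste0("db", l)]] <- params$decoder[[l]]$b
  }
  out$xi <- xi$values
  out
}

grads_to_list <- function(g) {
  out <- list()
  for (l in seq_along(g$encoder)) {
    out[[paste0("eW", l)]] <- unname(g$encoder[[l]]$W)
    out[[paste0("eb", l)]] <- unname(g$encoder[[l]]$b)
  }
  for (l in seq_along(g$decoder)) {
    out[[paste0("dW", l)]] <- unname(g$decoder[[l]]$W)
    out[[paste0("db", l)]] <- unname(g$decoder[[l]]$b)
  }
  out$xi <- unname(g$xi)
  out
}

list_to_params <- function(flat, params, xi) {
  for (l in seq_along(params$encoder)) {
    params$encoder[[l]]$W <- flat[[paste0("eW", l)]]
    params$encoder[[l]]$b <- flat[[paste0("eb", l)]]
  }
  for (l in seq_along(params$decoder)) {
    params$decoder[[l]]$W <- flat[[paste0("dW", l)]]
    params$decoder[[l]]$b <- flat[[paste0("db", l)]]
  }
  xi <- coefficient_matrix(flat$xi * xi$mask, xi$mask,
                           terms = rownames(xi$values))
  list(params = params, xi = xi)
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

record_history <- function(history, epoch, phase, params, spec, xi, weights,
                           train_ds, val_ds) {
  tr <- loss_terms(params, spec, xi, train_ds)
  row <- data.frame(epoch = epoch, phase = phase, split = "train",
                    recon = tr$recon, sindy_z = tr$sindy_z,
                    sindy_x = tr$sindy_x, l1 = tr$l1,
                    total = total_loss(tr, weights),
                    active_terms = active_term_count(xi))
  if (!is.null(val_ds)) {
    va <- loss_terms(params, spec, xi, val_ds)
    row <- rbind(row, data.frame(epoch = epoch, phase = phase, split = "val",
                                 recon = va$recon, sindy_z = va$sindy_z,
                                 sindy_x = va$sindy_x, l1 = va$l1,
                                 total = total_loss(va, weights),
                                 active_terms = active_term_count(xi)))
  }
  rbind(history, row)
}

#' Train a SINDy autoencoder
#'
#' Runs minibatch Adam on the composite objective (see
#' \code{\link{loss_weights}}), applying sequential thresholding to the
#' coefficient matrix every \code{threshold_interval} epochs, then an optional
#' refinement phase with the L1 penalty switched off and the mask frozen.
#' Fully reproducible given \code{config$seed} (single-threaded BLAS).
#'
#' @param dataset A \code{\link{snapshot_dataset}}; must carry \code{ddX}
#'   when the library spec has model order 2.
#' @param config A \code{\link{training_config}}.
#' @param params Optional pre-initialized network (otherwise drawn from
#'   \code{config$seed}).
#' @return An object of class \code{sindy_ae_model}: fields \code{params},
#'   \code{spec}, \code{xi}, \code{config}, \code{history} (per-epoch loss
#'   breakdown data frame), \code{final_loss} (train/val breakdowns).
#' @export
train_sindy_ae <- function(dataset, config, params = NULL) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  spec <- config$spec
  weights <- config$weights
  n <- ncol(dataset$X)
  if (is.null(params)) {
    params <- init_network(n, spec$latent_dim, config$hidden_widths,
                           config$activation, seed = config$seed)
  }
  xi <- coefficient_matrix(matrix(1, library_size(spec), spec$latent_dim),
                           matrix(1, library_size(spec), spec$latent_dim),
                           terms = library_terms(spec))
  split <- dataset_split(dataset, config$validation_fraction)
  train_ds <- dataset_slice(dataset, split$train)
  val_ds <- if (length(split$val) > 0) dataset_slice(dataset, split$val)
  m <- nrow(train_ds$X)
  bs <- min(config$batch_size, m)
  flat <- params_to_list(params, xi)
  state <- adam_init(flat)
  history <- NULL
  run_epochs <- function(n_epochs, phase, weights, thresholding, flat, state,
                         params, xi, history) {
    if (n_epochs > 0) for (epoch in seq_len(n_epochs)) {
      perm <- sample.int(m)
      starts <- seq(1, m, by = bs)
      for (s in starts) {
        idx <- perm[s:min(s + bs - 1, m)]
        batch <- dataset_slice(train_ds, idx)
        g <- tryCatch(
          sae_backward(params, spec, xi, batch, weights),
          error = function(e) stop(sprintf(
            "training aborted at %s epoch %d: %s", phase, epoch,
            conditionMessage(e)), call. = FALSE)
        )
        check_finite_epoch(g$terms, phase, epoch)
        upd <- adam_step(flat, grads_to_list(g), state, config$learning_rate)
        flat <- upd$flat; state <- upd$state
        pk <- list_to_params(flat, params, xi)
        params <- pk$params; xi <- pk$xi
      }
      if (thresholding && config$threshold > 0 &&
          epoch %% config$threshold_interval == 0) {
        xi <- apply_threshold(xi, config$threshold)
        flat$xi <- xi$values
      }
      if (epoch %% config$history_interval == 0 || epoch == n_epochs) {
        history <- record_history(history, epoch, phase, params, spec, xi,
                                  weights, train_ds, val_ds)
      }
    }
    list(flat = flat, state = state, params = params, xi = xi,
         history = history)
  }
  st <- run_epochs(config$epochs, "train", weights, TRUE,
                   flat, state, params, xi, history)
  if (config$refinement_epochs > 0) {
    refine_w <- weights; refine_w$lambda3 <- 0
    st <- run_epochs(config$refinement_epochs, "refine", refine_w, FALSE,
                     st$flat, st$state, st$params, st$xi, st$history)
  }
  final <- list(
    train = loss_terms(st$params, spec, st$xi, train_ds),
    val = if (!is.null(val_ds)) loss_terms(st$params, spec, st$xi, val_ds)
  )
  structure(list(params = st$params, spec = spec, xi = st$xi, config = config,
                 history = st$history, final_loss = final,
                 validation_total = if (!is.null(final$val))
                   total_loss(final$val, weights) else
                   total_loss(final$train, weights)),
            class = "sindy_ae_model")
}

check_finite_epoch <- function(terms, phase, epoch) {
  for (nm in names(terms)) {
    if (!is.finite(terms[[nm]])) {
      stop(sprintf("non-finite loss term '%s' at %s epoch %d", nm, phase,
                   epoch), call. = FALSE)
    }
  }
}

#' @export
print.sindy_ae_model <- function(x, ...) {
  cat(sprintf("<sindy_ae_model> d = %d, %d active terms, validation total loss %.3g\n",
              x$spec$latent_dim, active_term_count(x$xi), x$validation_total))
  print(x$xi)
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.sindy_ae_model <- function(x, ...) {
  fl <- x$final_loss$train
  tibble::tibble(
    latent_dim = x$spec$latent_dim,
    active_terms = active_term_count(x$xi),
    recon = fl$recon, sindy_z = fl$sindy_z, sindy_x = fl$sindy_x, l1 = fl$l1,
    total = total_loss(fl, x$config$weights),
    validation_total = x$validation_total,
    epochs = x$config$epochs, seed = x$config$seed
  )
}

#' @export
tidy.sindy_ae_model <- function(x, ...) {
  tidy(x$xi)
}

#' Train several seeded instances and keep the best
#'
#' Multiple restarts are part of the method's protocol: sparsification is
#' sensitive to initialization, so several instances are trained with seeds
#' \code{config$seed + 0 .. n_instances - 1} and the one with the lowest
#' validation total loss is selected. Per-instance failures are caught and
#' reported; the call fails only if every instance fails.
#'
#' @param dataset A \code{\link{snapshot_dataset}}.
#' @param config A \code{\link{training_config}}.
#' @param n_instances Number of seeded runs (>= 1).
#' @return List with \code{best} (a \code{sindy_ae_model}), \code{all}
#'   (per-instance models or error conditions), \code{errors} (indices of
#'   failed instances).
#' @export
train_ensemble <- function(dataset, config, n_instances = 1) {
  stopifnot(n_instances >= 1)
  all <- vector("list", n_instances)
  errs <- integer(0)
  for (i in seq_len(n_instances)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    all[[i]] <- tryCatch(train_sindy_ae(dataset, cfg), error = function(e) e)
    if (inherits(all[[i]], "error")) {
      warning(sprintf("instance %d (seed %d) failed: %s", i, cfg$seed,
                      conditionMessage(all[[i]])))
      errs <- c(errs, i)
    }
  }
  ok <- which(!vapply(all, inherits, logical(1), "error"))
  if (length(ok) == 0) stop("train_ensemble: all instances failed", call. = FALSE)
  vt <- vapply(all[ok], function(mdl) mdl$validation_total, numeric(1))
  list(best = all[[ok[which.min(vt)]]], all = all, errors = errs)
}
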