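#' Relative L2 error
#'
#' \eqn{\|truth - estimate\|_2 / \|truth\|_2}, computed over the flattened
#' arrays (the whole test set at once).
#'
#' @param truth,estimate Arrays of equal shape; \code{truth} must not be
#'   identically zero.
#' @return Non-negative scalar.
#' @export
relative_l2 <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate))
  denom <- sqrt(sum(truth^2))
  if (denom == 0) {
    stop("relative_l2: truth has zero norm; metric undefined", call. = FALSE)
  }
  sqrt(sum((truth - estimate)^2)) / denom
}

#' Evaluate a trained model on a test dataset
#'
#' Computes the relative L2 errors of the reconstruction
#' (\code{rel_err_x}), the derivative reconstruction through the decoder
#' Jacobian (\code{rel_err_dx}; \code{rel_err_ddx} for order-2 models), the
#' latent-derivative prediction \eqn{\Theta\Xi} against the encoded
#' derivatives (\code{rel_err_dz} / \code{rel_err_ddz}), and the simulation
#' error \code{rel_err_z_sim}: each test trajectory's latent model is
#' integrated from its encoded initial condition over the trajectory's time
#' grid and compared with the encoded truth. Trajectories whose simulation
#' blows up are recorded in \code{sim_failure_fraction} instead of aborting.
#'
#' @param model A \code{sindy_ae_model} (from \code{\link{train_sindy_ae}})
#'   or a list with fields \code{params}, \code{spec}, \code{xi}.
#' @param test A \code{\link{snapshot_dataset}} with trajectory labels and
#'   times (needed for the simulation metric).
#' @return A list of class \code{evaluation_report}.
#' @export
evaluate_model <- function(model, test) {
  params <- model$params; spec <- model$spec; xi <- model$xi
  order2 <- spec$model_order == 2
  if (order2 && is.null(test$ddX)) {
    stop("evaluate_model: order-2 model needs ddX in the test set",
         call. = FALSE)
  }
  if (order2) {
    pr <- propagate_second(params, test$X, test$dX, test$ddX)
    Z <- pr$z; dZ <- pr$dz; target_z <- pr$ddz
    Theta <- build_library(cbind(Z, dZ), spec)
    pred <- Theta %*% xi$values
    rec <- propagate_ddx(params, Z, dZ, pred)
    Xhat <- rec$xhat
    rep_err <- list(
      rel_err_x = relative_l2(test$X, Xhat),
      rel_err_ddx = relative_l2(test$ddX, rec$ddx),
      rel_err_ddz = relative_l2(target_z, pred)
    )
  } else {
    pr <- propagate_dz(params, test$X, test$dX)
    Z <- pr$z; dZ <- pr$dz
    Theta <- build_library(Z, spec)
    pred <- Theta %*% xi$values
    Xhat <- decode(params, Z)
    dXpred <- propagate_dx(params, Z, pred)
    rep_err <- list(
      rel_err_x = relative_l2(test$X, Xhat),
      rel_err_dx = relative_l2(test$dX, dXpred),
      rel_err_dz = relative_l2(dZ, pred)
    )
  }
  sim <- sim_latent_error(params, spec, xi, test, Z, dZ)
  out <- c(rep_err, sim,
           list(active_terms = active_term_count(xi)))
  structure(out, class = "evaluation_report")
}

# latent simulation error pooled over test trajectories; blow-ups counted,
# not fatal
sim_latent_error <- function(params, spec, xi, test, Z, dZ) {
  if (is.null(test$traj_id) || is.null(test$times)) {
    return(list(rel_err_z_sim = NA_real_, sim_failure_fraction = NA_real_))
  }
  ids <- unique(test$traj_id)
  num <- 0; den <- 0; fails <- 0
  for (id in ids) {
    idx <- which(test$traj_id == id)
    tt <- test$times[idx]
    ztrue <- Z[idx, , drop = FALSE]
    sim <- tryCatch({
      if (spec$model_order == 2) {
        simulate_model(spec, xi, ztrue[1, ], dZ[idx[1], ], times = tt)
      } else {
        simulate_model(spec, xi, ztrue[1, ], times = tt)
      }
    }, error = function(e) NULL)
    if (is.null(sim) || !all(is.finite(sim$z))) {
      fails <- fails + 1
      next
    }
    num <- num + sum((ztrue - sim$z)^2)
    den <- den + sum(ztrue^2)
  }
  list(
    rel_err_z_sim = if (den > 0 && fails < length(ids))
      sqrt(num / den) else NA_real_,
    sim_failure_fraction = fails / length(ids)
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]], digits = 4)))
  }
  invisible(x)
}

#' Reference sparsity pattern of a known system
#'
#' @param values \eqn{p \times d} matrix of reference coefficients in the
#'   canonical term ordering of \code{spec} (zeros for inactive terms).
#' @param spec The \code{\link{library_spec}} fixing the ordering.
#' @return An object of class \code{reference_pattern} with the binary
#'   support and the reference values.
#' @export
reference_pattern <- function(values, spec) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == library_size(spec),
            ncol(values) == spec$latent_dim)
  rownames(values) <- library_terms(spec)
  structure(list(support = (values != 0) * 1, values = values, spec = spec),
            class = "reference_pattern")
}

#' Reference coefficients of the Lorenz system
#'
#' The 7-term support of the Lorenz equations laid out in the canonical
#' ordering of an order-1 polynomial library in three variables.
#'
#' @param spec A d = 3, model-order-1 \code{\link{library_spec}} with
#'   \code{poly_order >= 2}.
#' @param sigma,rho,beta Lorenz parameters.
#' @return A \code{\link{reference_pattern}}.
#' @export
lorenz_reference <- function(spec = library_spec(3, poly_order = 3),
                             sigma = 10, rho = 28, beta = 8 / 3) {
  stopifnot(spec$latent_dim == 3, spec$model_order == 1, spec$poly_order >= 2)
  terms <- library_terms(spec)
  V <- matrix(0, library_size(spec), 3)
  rownames(V) <- terms
  V["z1", 1] <- -sigma; V["z2", 1] <- sigma
  V["z1", 2] <- rho; V["z2", 2] <- -1; V["z1*z3", 2] <- -1
  V["z1*z2", 3] <- 1; V["z3", 3] <- -beta
  reference_pattern(V, spec)
}

#' Reference pattern of the nonlinear pendulum
#'
#' \eqn{\ddot z = -\sin z}: a single active term in an order-2 library with
#' sine terms.
#'
#' @param spec A d = 1, model-order-2 \code{\link{library_spec}} with
#'   \code{include_sine = TRUE}.
#' @return A \code{\link{reference_pattern}}.
#' @export
pendulum_reference <- function(spec = library_spec(1, poly_order = 3,
                                                   include_sine = TRUE,
                                                   model_order = 2)) {
  stopifnot(spec$latent_dim == 1, spec$model_order == 2, spec$include_sine)
  V <- matrix(0, library_size(spec), 1)
  rownames(V) <- library_terms(spec)
  V["sin(z1)", 1] <- -1
  reference_pattern(V, spec)
}

# transform coefficients under z'_i = a_i z_i (optionally after a coordinate
# permutation perm applied to the latent axes): monomial term with exponents e
# in equation i picks up a factor a_i / prod(a^e); sine terms only admit
# a = +/-1 exactly, and flip sign with odd arguments: sin(z_j) -> sin(z'_j/a_j)
# equals a_j^{-1}-scaled argument, representable in the same library only for
# |a_j| = 1 where sin(-x) = -sin(x).
transform_coefficients <- function(xi_values, spec, scales, perm = NULL) {
  d <- spec$latent_dim
  k <- library_input_width(spec)
  if (is.null(perm)) perm <- seq_len(d)
  # permute: new coordinate i is old coordinate perm[i]
  # scales apply per latent axis; for order-2 libraries dz_i scales like z_i
  ax_scale <- rep(scales, spec$model_order)
  V <- xi_values
  # permute columns (equations) and the variable identity inside terms:
  # build index map of library terms under variable permutation
  perm_full <- c(perm, if (spec$model_order == 2) perm + d)
  term_perm <- library_permutation_index(spec, perm_full)
  V <- V[term_perm, perm, drop = FALSE]
  out <- V
  col <- 0L
  if (spec$include_constant) {
    col <- col + 1L
    out[col, ] <- V[col, ] * scales
  }
  if (spec$poly_order >= 1) {
    for (e in monomial_exponents(k, spec$poly_order)) {
      col <- col + 1L
      denom <- prod(ax_scale^e)
      out[col, ] <- V[col, ] * scales / denom
    }
  }
  if (spec$include_sine) {
    for (j in seq_len(k)) {
      col <- col + 1L
      out[col, ] <- V[col, ] * scales * sign(ax_scale[j])
    }
  }
  rownames(out) <- library_terms(spec)
  out
}

# Row-index map for the variable change z'_i = z_{perm_full[i]} (scales
# handled separately): entry r of the result is the old library row whose
# term, rewritten in the new variables, lands in new row r. For a monomial
# with new exponents e', the old exponents satisfy e[perm[i]] = e'[i], i.e.
# e = e'[order(perm)].
library_permutation_index <- function(spec, perm_full) {
  k <- library_input_width(spec)
  inv <- order(perm_full)
  idx <- integer(0)
  base <- 0L
  if (spec$include_constant) { idx <- 1L; base <- 1L }
  if (spec$poly_order >= 1) {
    exps <- monomial_exponents(k, spec$poly_order)
    tab <- stats::setNames(seq_along(exps),
                           vapply(exps, paste, character(1), collapse = ","))
    for (e_new in exps) {
      e_old <- e_new[inv]
      idx <- c(idx, base + tab[[paste(e_old, collapse = ",")]])
    }
    base <- base + length(exps)
  }
  if (spec$include_sine) {
    idx <- c(idx, base + perm_full)
  }
  idx
}

#' Sparsity-pattern match under per-axis rescaling and permutation
#'
#' Decides whether a discovered coefficient matrix has the same sparsity
#' pattern as a reference system after an invertible per-coordinate variable
#' change \eqn{z'_i = a_i z_{\pi(i)}} (scaling, sign flips, and axis
#' permutation — latent axes carry no intrinsic order or scale). For
#' polynomial terms a pure scaling never changes the support, so support
#' equivalence is decided over permutations with sign/scale freedom; when
#' reference coefficient values are available the scales are fit numerically
#' and the maximum relative coefficient deviation under the best transform is
#' reported.
#'
#' @param xi A \code{\link{coefficient_matrix}}.
#' @param ref A \code{\link{reference_pattern}}.
#' @param spec The \code{\link{library_spec}} shared by both.
#' @return A list: \code{identified} (flag), \code{perm}, \code{scales},
#'   \code{transformed} (coefficients after the best transform),
#'   \code{max_rel_dev} (NA when the reference has no values).
#' @export
match_sparsity <- function(xi, ref, spec) {
  d <- spec$latent_dim
  stopifnot(nrow(xi$values) == library_size(spec))
  perms <- all_permutations(d)
  has_vals <- any(ref$values != 0)
  best <- NULL
  for (pi in perms) {
    # support under permutation (scaling cannot change polynomial support;
    # sine support survives only under |a| = 1, which the family includes)
    sup <- transform_support(xi$mask, spec, pi)
    if (!all(sup == ref$support)) next
    if (!has_vals) {
      return(list(identified = TRUE, perm = pi, scales = rep(1, d),
                  transformed = transform_coefficients(xi$values, spec,
                                                       rep(1, d), pi),
                  max_rel_dev = NA_real_))
    }
    fit <- fit_scales(xi$values, ref, spec, pi)
    if (is.null(best) || fit$max_rel_dev < best$max_rel_dev) {
      best <- c(list(identified = TRUE, perm = pi), fit)
    }
  }
  if (is.null(best)) {
    return(list(identified = FALSE, perm = NULL, scales = NULL,
                transformed = NULL, max_rel_dev = NA_real_))
  }
  best
}

transform_support <- function(mask, spec, perm) {
  d <- spec$latent_dim
  perm_full <- c(perm, if (spec$model_order == 2) perm + d)
  ip <- library_permutation_index(spec, perm_full)
  mask[ip, perm, drop = FALSE]
}

all_permutations <- function(d) {
  if (d == 1) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (length(rest) == 0) {
      out[[length(out) + 1]] <<- prefix
    } else {
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
  }
  rec(integer(0), seq_len(d))
  out
}

# fit per-axis scales minimizing squared relative deviation of active
# coefficients from the reference values, trying all sign patterns
fit_scales <- function(xi_values, ref, spec, perm) {
  d <- spec$latent_dim
  act <- which(ref$support != 0)
  objective <- function(a) {
    tv <- transform_coefficients(xi_values, spec, a, perm)
    dev <- (tv[act] - ref$values[act]) / ref$values[act]
    sum(dev^2)
  }
  best <- NULL
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), d)))
  for (srow in seq_len(nrow(signs))) {
    s <- signs[srow, ]
    opt <- stats::optim(rep(0, d), function(la) objective(s * exp(la)),
                        method = if (d == 1) "Brent" else "Nelder-Mead",
                        lower = if (d == 1) -10 else -Inf,
                        upper = if (d == 1) 10 else Inf,
                        control = list(maxit = 2000, reltol = 1e-12))
    a <- s * exp(opt$par)
    tv <- transform_coefficients(xi_values, spec, a, perm)
    mrd <- max(abs((tv[act] - ref$values[act]) / ref$values[act]))
    if (is.null(best) || mrd < best$max_rel_dev) {
      best <- list(scales = a, transformed = tv, max_rel_dev = mrd)
    }
  }
  best
}
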