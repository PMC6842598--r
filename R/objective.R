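#' Loss weights for the composite training objective
#'
#' The objective is
#' \deqn{L_{recon} + \lambda_1 L_{dx/dt} + \lambda_2 L_{dz/dt} + \lambda_3
#' L_{reg},}
#' where \eqn{L_{recon} = \|x - \psi(\varphi(x))\|_2^2} is the autoencoder
#' reconstruction error, \eqn{L_{dx/dt}} penalizes the error in
#' reconstructing \eqn{\dot x} through the decoder Jacobian,
#' \eqn{L_{dz/dt}} penalizes the mismatch between the encoded velocities and
#' the library model \eqn{\Theta(z)\Xi}, and \eqn{L_{reg}} is the L1 norm of
#' the active coefficients. \eqn{\lambda_1} pairs with the x-derivative term
#' and \eqn{\lambda_2} with the z-derivative term.
#'
#' Defaults are package choices tuned for the shipped benchmarks, not
#' published values.
#'
#' @param lambda1 Weight on the \eqn{\dot x} reconstruction term.
#' @param lambda2 Weight on the \eqn{\dot z} prediction term.
#' @param lambda3 Weight on the L1 coefficient penalty.
#' @return An object of class \code{loss_weights}.
#' @export
loss_weights <- function(lambda1 = 5e-4, lambda2 = 5e-5, lambda3 = 1e-5) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3),
            class = "loss_weights")
}

#' Evaluate the four loss terms on a batch
#'
#' Each squared-error term is a mean over batch rows of the squared L2 norm
#' over coordinates (mean-over-batch keeps the weights batch-size
#' independent). The L1 term sums |coefficient| over mask-active entries
#' only, so the penalty never fights the thresholding mask. For model order 2
#' the derivative terms use \eqn{\ddot x} and \eqn{\ddot z} in place of
#' \eqn{\dot x}, \eqn{\dot z}.
#'
#' @param params A \code{\link{init_network}} object.
#' @param spec A \code{\link{library_spec}}.
#' @param xi A \code{\link{coefficient_matrix}}.
#' @param batch A \code{\link{snapshot_dataset}} (or slice).
#' @return A list of class \code{loss_breakdown} with unweighted fields
#'   \code{recon}, \code{sindy_z}, \code{sindy_x}, \code{l1}.
#' @export
loss_terms <- function(params, spec, xi, batch) {
  fb <- sae_forward(params, spec, xi, batch)
  check_finite_terms(fb$terms)
  fb$terms
}

check_finite_terms <- function(terms) {
  for (nm in names(terms)) {
    if (!is.finite(terms[[nm]])) {
      stop(sprintf("non-finite loss term '%s'", nm), call. = FALSE)
    }
  }
  invisible(terms)
}

#' Combine loss terms into the weighted total
#'
#' @param breakdown A \code{loss_breakdown} from \code{\link{loss_terms}}.
#' @param weights A \code{\link{loss_weights}}.
#' @return Scalar \code{recon + lambda1*sindy_x + lambda2*sindy_z +
#'   lambda3*l1}.
#' @export
total_loss <- function(breakdown, weights) {
  breakdown$recon + weights$lambda1 * breakdown$sindy_x +
    weights$lambda2 * breakdown$sindy_z + weights$lambda3 * breakdown$l1
}

# Forward pass of the full objective. Returns the terms plus every
# intermediate needed by sae_backward().
sae_forward <- function(params, spec, xi, batch) {
  m <- nrow(batch$X)
  order2 <- spec$model_order == 2
  if (order2 && is.null(batch$ddX)) {
    stop("model order 2 requires ddX in the dataset", call. = FALSE)
  }
  if (order2) check_order2_activation(params)
  enc <- nn_forward(params$encoder, params$activation, batch$X, batch$dX,
                    if (order2) batch$ddX)
  Z <- enc$h
  lib_in <- if (order2) cbind(Z, enc$dh) else Z
  Theta <- build_library(lib_in, spec)
  pred <- Theta %*% xi$values
  dec <- if (order2) {
    nn_forward(params$decoder, params$activation, Z, enc$dh, pred)
  } else {
    nn_forward(params$decoder, params$activation, Z, pred)
  }
  target_z <- if (order2) enc$ddh else enc$dh
  target_x <- if (order2) batch$ddX else batch$dX
  pred_x <- if (order2) dec$ddh else dec$dh
  terms <- structure(list(
    recon = sum((batch$X - dec$h)^2) / m,
    sindy_z = sum((target_z - pred)^2) / m,
    sindy_x = sum((target_x - pred_x)^2) / m,
    l1 = sum(abs(xi$values[xi$mask != 0]))
  ), class = "loss_breakdown")
  list(terms = terms, enc = enc, dec = dec, Z = Z, lib_in = lib_in,
       Theta = Theta, pred = pred, target_z = target_z, target_x = target_x,
       pred_x = pred_x, m = m, order2 = order2)
}

# Reverse pass of the weighted objective. Returns gradients w.r.t. encoder
# layers, decoder layers and the coefficient values (masked entries get 0).
sae_backward <- function(params, spec, xi, batch, weights, fw = NULL) {
  if (is.null(fw)) fw <- sae_forward(params, spec, xi, batch)
  m <- fw$m
  GXhat <- 2 * (fw$dec$h - batch$X) / m
  Gpred_x <- 2 * weights$lambda1 * (fw$pred_x - fw$target_x) / m
  if (fw$order2) {
    decB <- nn_backward(params$decoder, params$activation, fw$dec$cache,
                        GXhat, NULL, Gpred_x)
  } else {
    decB <- nn_backward(params$decoder, params$activation, fw$dec$cache,
                        GXhat, Gpred_x)
  }
  # gradient hitting the library prediction Theta %*% Xi: decoder input
  # derivative path plus the direct z-derivative mismatch term
  Gpred <- 2 * weights$lambda2 * (fw$pred - fw$target_z) / m
  Gpred <- Gpred + (if (fw$order2) decB$Gddh_in else decB$Gdh_in)
  Gxi <- (crossprod(fw$Theta, Gpred) +
            weights$lambda3 * sign(xi$values)) * xi$mask
  GTheta <- Gpred %*% t(xi$values)
  Glib <- library_vjp(fw$lib_in, spec, GTheta)
  Gtarget_z <- 2 * weights$lambda2 * (fw$target_z - fw$pred) / m
  d <- spec$latent_dim
  if (fw$order2) {
    GZ <- decB$Gh_in + Glib[, 1:d, drop = FALSE]
    GdZ <- Glib[, (d + 1):(2 * d), drop = FALSE]
    if (!is.null(decB$Gdh_in)) GdZ <- GdZ + decB$Gdh_in
    encB <- nn_backward(params$encoder, params$activation, fw$enc$cache,
                        GZ, GdZ, Gtarget_z)
  } else {
    GZ <- decB$Gh_in + Glib
    encB <- nn_backward(params$encoder, params$activation, fw$enc$cache,
                        GZ, Gtarget_z)
  }
  list(encoder = encB$grads, decoder = decB$grads, xi = Gxi,
       terms = fw$terms)
}
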