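#' Sequentially thresholded least squares
#'
#' The classic SINDy sparse regression: fit \eqn{\Xi} by ordinary least
#' squares, zero every coefficient with magnitude below \code{threshold},
#' refit on the surviving support, and repeat until the support is stable or
#' \code{max_iter} is reached. A proxy for L0-penalized regression.
#'
#' Rank-deficient active submatrices are solved by minimum-norm least squares
#' (SVD pseudoinverse) with a warning. When there are fewer rows than library
#' columns the regression is underdetermined; a warning (not an error) is
#' emitted because the method only assumes, and does not require, m >> p.
#'
#' @param Theta \eqn{m \times p} library matrix (see
#'   \code{\link{build_library}}).
#' @param targets \eqn{m \times d} matrix of time derivatives to regress onto
#'   the library.
#' @param threshold Non-negative magnitude cutoff.
#' @param max_iter Maximum number of threshold/refit rounds (default 10; the
#'   loop stops early when the support stops changing).
#' @return A \code{\link{coefficient_matrix}} whose mask is the final support.
#' @examples
#' spec <- library_spec(1, poly_order = 2)
#' z <- matrix(seq(-1, 1, length.out = 50))
#' xi <- stlsq(build_library(z, spec), -z, threshold = 0.1)  # recovers dz = -z
#' @export
stlsq <- function(Theta, targets, threshold, max_iter = 10) {
  Theta <- as.matrix(Theta)
  targets <- as.matrix(targets)
  stopifnot(nrow(Theta) == nrow(targets), threshold >= 0, max_iter >= 1)
  m <- nrow(Theta); p <- ncol(Theta); d <- ncol(targets)
  if (m < p) {
    warning(sprintf("stlsq: %d samples for %d library terms; system is underdetermined",
                    m, p))
  }
  Xi <- lstsq(Theta, targets)
  mask <- matrix(1, p, d)
  for (iter in seq_len(max_iter)) {
    small <- abs(Xi) < threshold
    new_mask <- mask * (!small)
    if (all(new_mask == mask) && iter > 1) break
    support_changed <- any(new_mask != mask)
    mask <- new_mask
    Xi <- matrix(0, p, d)
    for (j in seq_len(d)) {
      act <- which(mask[, j] != 0)
      if (length(act) > 0) {
        Xi[act, j] <- lstsq(Theta[, act, drop = FALSE],
                            targets[, j, drop = FALSE])
      }
    }
    if (!support_changed && iter > 1) break
  }
  coefficient_matrix(Xi * mask, mask,
                     terms = colnames(Theta))
}

# least squares with minimum-norm fallback for rank-deficient systems
lstsq <- function(A, B) {
  B <- as.matrix(B)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    warning("lstsq: rank-deficient system; using minimum-norm solution")
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * max(sv$d)
    keep <- sv$d > tol
    dinv <- ifelse(keep, 1 / sv$d, 0)
    return(sv$v %*% (dinv * (t(sv$u) %*% B)))
  }
  qr.coef(qrA, B)
}

#' Right-hand side of a discovered latent model
#'
#' Evaluates \eqn{\Theta(\text{state}) \Xi}: the latent velocity \eqn{\dot z}
#' for model order 1, or the latent acceleration \eqn{\ddot z} for model
#' order 2 (where \code{state} is the concatenation \eqn{(z, \dot z)}).
#'
#' @param state Numeric vector whose length is the spec's input width.
#' @param spec A \code{\link{library_spec}}.
#' @param xi A \code{\link{coefficient_matrix}}.
#' @return Numeric vector of length \code{spec$latent_dim}.
#' @export
sindy_rhs <- function(state, spec, xi) {
  k <- library_input_width(spec)
  if (length(state) != k) {
    stop(sprintf("sindy_rhs: state has length %d, spec expects %d",
                 length(state), k), call. = FALSE)
  }
  as.vector(build_library(matrix(state, nrow = 1), spec) %*% xi$values)
}

#' Latent trajectory container
#'
#' @param times Strictly increasing numeric vector of length m.
#' @param z \eqn{m \times d} state matrix.
#' @param dz \eqn{m \times d} velocity matrix.
#' @param ddz Optional \eqn{m \times d} acceleration matrix (order-2 systems).
#' @return An object of class \code{latent_trajectory}.
#' @export
latent_trajectory <- function(times, z, dz, ddz = NULL) {
  z <- as.matrix(z); dz <- as.matrix(dz)
  stopifnot(all(diff(times) > 0), nrow(z) == length(times),
            all(dim(dz) == dim(z)))
  if (!is.null(ddz)) {
    ddz <- as.matrix(ddz)
    stopifnot(all(dim(ddz) == dim(z)))
  }
  structure(list(times = times, z = z, dz = dz, ddz = ddz),
            class = "latent_trajectory")
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat(sprintf("<latent_trajectory> d = %d, %d time points on [%g, %g]%s\n",
              ncol(x$z), length(x$times), min(x$times), max(x$times),
              if (is.null(x$ddz)) "" else " (order 2)"))
  invisible(x)
}

#' Simulate a discovered latent dynamical system
#'
#' Integrates \eqn{\dot z = \Theta(z)\Xi} (or, for model order 2, the
#' first-order system of width \eqn{2d} equivalent to
#' \eqn{\ddot z = \Theta(z, \dot z)\Xi}) with an adaptive solver.
#'
#' @param spec A \code{\link{library_spec}}.
#' @param xi A \code{\link{coefficient_matrix}}.
#' @param z0 Initial state (length d).
#' @param dz0 Initial velocity; required for model order 2.
#' @param times Strictly increasing output times.
#' @param rtol,atol Solver tolerances. Defaults suit discovered-model
#'   simulation; pass tighter values (e.g. 1e-10/1e-12) for reference runs.
#' @return A \code{\link{latent_trajectory}}.
#' @export
simulate_model <- function(spec, xi, z0, dz0 = NULL, times,
                           rtol = 1e-6, atol = 1e-9) {
  stopifnot(all(diff(times) > 0))
  d <- spec$latent_dim
  stopifnot(length(z0) == d)
  if (spec$model_order == 2 && is.null(dz0)) {
    stop("simulate_model: model order 2 requires an initial velocity dz0",
         call. = FALSE)
  }
  if (spec$model_order == 1) {
    deriv <- function(t, y, parms) list(sindy_rhs(y, spec, xi))
    y0 <- as.numeric(z0)
  } else {
    stopifnot(length(dz0) == d)
    deriv <- function(t, y, parms) {
      acc <- sindy_rhs(y, spec, xi)
      list(c(y[(d + 1):(2 * d)], acc))
    }
    y0 <- c(as.numeric(z0), as.numeric(dz0))
  }
  sol <- suppressWarnings(
    deSolve::ode(y0, times, deriv, parms = NULL, method = "ode45",
                 rtol = rtol, atol = atol)
  )
  ok <- stats::complete.cases(sol) & apply(is.finite(sol), 1, all)
  if (!all(ok) || nrow(sol) < length(times)) {
    t_bad <- if (nrow(sol) < length(times)) times[nrow(sol) + 1] else
      sol[which(!ok)[1], 1]
    stop(sprintf("simulate_model: integration diverged near t = %g", t_bad),
         call. = FALSE)
  }
  y <- sol[, -1, drop = FALSE]
  if (spec$model_order == 1) {
    dz <- t(apply(y, 1, sindy_rhs, spec = spec, xi = xi))
    if (d == 1) dz <- matrix(dz, ncol = 1)
    latent_trajectory(times, y, dz)
  } else {
    z <- y[, 1:d, drop = FALSE]
    dz <- y[, (d + 1):(2 * d), drop = FALSE]
    ddz <- t(apply(y, 1, sindy_rhs, spec = spec, xi = xi))
    if (d == 1) ddz <- matrix(ddz, ncol = 1)
    latent_trajectory(times, z, dz, ddz)
  }
}
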