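#' Candidate-function library specification
#'
#' Defines the basis \eqn{\Theta(z) = [\theta_1(z), \ldots, \theta_p(z)]} used
#' to represent the latent dynamics \eqn{\dot z = \Theta(z)\Xi} (model order 1)
#' or \eqn{\ddot z = \Theta(z, \dot z)\Xi} (model order 2). Terms are, in this
#' fixed canonical order: the constant (if requested), all monomials of the
#' input variables up to \code{poly_order} in graded lexicographic order, then
#' one sine term per input variable (if requested).
#'
#' The ordering is frozen because the row identity of a coefficient matrix
#' depends on it: within each total degree, exponent vectors are enumerated
#' lexicographically with the first variable varying slowest, e.g. for two
#' variables at degree 2: \code{z1^2, z1*z2, z2^2}.
#'
#' @param latent_dim Latent dimension \eqn{d} (positive integer).
#' @param poly_order Maximum total degree of monomial terms (non-negative).
#' @param include_constant Include the constant term? Default \code{TRUE}.
#' @param include_sine Include \code{sin} of each input variable? Default
#'   \code{FALSE}.
#' @param model_order 1 for first-order dynamics in \eqn{z}; 2 for second-order
#'   dynamics, in which case library inputs are \eqn{(z, \dot z)} and the input
#'   width is \eqn{2d}.
#' @return An object of class \code{library_spec}.
#' @examples
#' spec <- library_spec(latent_dim = 3, poly_order = 2)
#' library_terms(spec)
#' @export
library_spec <- function(latent_dim, poly_order = 3, include_constant = TRUE,
                         include_sine = FALSE, model_order = 1) {
  stopifnot(latent_dim >= 1, poly_order >= 0, model_order %in% c(1, 2))
  spec <- structure(
    list(
      latent_dim = as.integer(latent_dim),
      poly_order = as.integer(poly_order),
      include_constant = isTRUE(include_constant),
      include_sine = isTRUE(include_sine),
      model_order = as.integer(model_order)
    ),
    class = "library_spec"
  )
  spec
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf(
    "<library_spec> d = %d, poly order %d, constant %s, sine %s, model order %d (%d terms)\n",
    x$latent_dim, x$poly_order, x$include_constant, x$include_sine,
    x$model_order, library_size(x)
  ))
  invisible(x)
}

# width of the matrix build_library() expects: d for order 1, 2d for order 2
library_input_width <- function(spec) {
  spec$latent_dim * spec$model_order
}

# exponent vectors of all monomials in k variables with total degree 1..q,
# graded lexicographic (degree-major, then lex with variable 1 slowest)
monomial_exponents <- function(k, q) {
  out <- list()
  if (q < 1) return(out)
  combos_of_degree <- function(k, g) {
    if (k == 1) return(list(g))
    res <- list()
    for (e1 in g:0) {
      for (rest in combos_of_degree(k - 1, g - e1)) {
        res[[length(res) + 1]] <- c(e1, rest)
      }
    }
    res
  }
  for (g in 1:q) out <- c(out, combos_of_degree(k, g))
  out
}

#' Number of terms in a library
#'
#' Closed form: \eqn{p = \binom{k + q}{q}} monomials including the constant
#' (with \eqn{k} the input width and \eqn{q} the polynomial order), minus one
#' if the constant is excluded, plus \eqn{k} sine terms if requested.
#'
#' @param spec A \code{\link{library_spec}}.
#' @return Integer term count \eqn{p}.
#' @export
library_size <- function(spec) {
  k <- library_input_width(spec)
  p <- choose(k + spec$poly_order, spec$poly_order)
  if (!spec$include_constant) p <- p - 1
  if (spec$include_sine) p <- p + k
  as.integer(p)
}

#' Canonical term names of a library
#'
#' @param spec A \code{\link{library_spec}}.
#' @return Character vector like \code{c("1", "z1", "z1*z2", "sin(z1)")}; for
#'   model order 2 the second block of variables is named \code{dz1, dz2, ...}.
#' @export
library_terms <- function(spec) {
  k <- library_input_width(spec)
  d <- spec$latent_dim
  vars <- if (spec$model_order == 2) {
    c(paste0("z", seq_len(d)), paste0("dz", seq_len(d)))
  } else {
    paste0("z", seq_len(d))
  }
  nm <- character(0)
  if (spec$include_constant) nm <- "1"
  if (spec$poly_order >= 1) {
    for (e in monomial_exponents(k, spec$poly_order)) {
      pieces <- character(0)
      for (j in seq_len(k)) {
        if (e[j] == 1) pieces <- c(pieces, vars[j])
        if (e[j] > 1) pieces <- c(pieces, paste0(vars[j], "^", e[j]))
      }
      nm <- c(nm, paste(pieces, collapse = "*"))
    }
  }
  if (spec$include_sine) nm <- c(nm, paste0("sin(", vars, ")"))
  nm
}

#' Evaluate the candidate-function library on data
#'
#' Row-wise evaluation of every candidate term on a matrix of latent states
#' (or latent states and velocities for model order 2).
#'
#' @param Z Numeric matrix (m rows) whose column count equals the spec's input
#'   width (\eqn{d}, or \eqn{2d} for model order 2). A vector is treated as a
#'   single row.
#' @param spec A \code{\link{library_spec}}.
#' @return An \eqn{m \times p} matrix with columns in canonical term order.
#' @examples
#' spec <- library_spec(2, poly_order = 2)
#' build_library(c(1, 2), spec)  # 1, z1, z2, z1^2, z1*z2, z2^2
#' @export
build_library <- function(Z, spec) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  k <- library_input_width(spec)
  if (ncol(Z) != k) {
    stop(sprintf("build_library: input has %d columns, spec expects %d",
                 ncol(Z), k), call. = FALSE)
  }
  m <- nrow(Z)
  cols <- list()
  if (spec$include_constant) cols[[length(cols) + 1]] <- rep(1, m)
  if (spec$poly_order >= 1) {
    for (e in monomial_exponents(k, spec$poly_order)) {
      v <- rep(1, m)
      for (j in seq_len(k)) if (e[j] > 0) v <- v * Z[, j]^e[j]
      cols[[length(cols) + 1]] <- v
    }
  }
  if (spec$include_sine) {
    for (j in seq_len(k)) cols[[length(cols) + 1]] <- sin(Z[, j])
  }
  Theta <- if (length(cols) == 0) matrix(numeric(0), m, 0) else
    do.call(cbind, cols)
  colnames(Theta) <- library_terms(spec)
  Theta
}

# vector-Jacobian product of build_library: given the gradient G (m x p) of a
# scalar loss w.r.t. Theta, accumulate the gradient w.r.t. Z (m x k)
library_vjp <- function(Z, spec, G) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  k <- library_input_width(spec)
  m <- nrow(Z)
  GZ <- matrix(0, m, k)
  col <- 0L
  if (spec$include_constant) col <- col + 1L
  if (spec$poly_order >= 1) {
    for (e in monomial_exponents(k, spec$poly_order)) {
      col <- col + 1L
      for (j in seq_len(k)) {
        if (e[j] > 0) {
          v <- rep(e[j], m)
          for (l in seq_len(k)) {
            pw <- if (l == j) e[l] - 1 else e[l]
            if (pw > 0) v <- v * Z[, l]^pw
          }
          GZ[, j] <- GZ[, j] + G[, col] * v
        }
      }
    }
  }
  if (spec$include_sine) {
    for (j in seq_len(k)) {
      col <- col + 1L
      GZ[, j] <- GZ[, j] + G[, col] * cos(Z[, j])
    }
  }
  GZ
}
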