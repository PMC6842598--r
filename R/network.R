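#' Initialize an autoencoder network
#'
#' Builds the feedforward encoder \eqn{\varphi: R^n \to R^d} and decoder
#' \eqn{\psi: R^d \to R^n} as mirrored stacks of affine layers. Hidden layers
#' use the chosen activation; the final layer of each stack is affine so the
#' latent coordinates and reconstructions span the data range. Weights are
#' variance-scaled random normals (sd \eqn{1/\sqrt{\text{fan-in}}}), biases
#' zero; initialization is deterministic given \code{seed}.
#'
#' @param n Input width (number of measurement coordinates).
#' @param d Latent width; \code{d <= n}.
#' @param hidden_widths Integer vector of encoder hidden-layer widths (the
#'   decoder mirrors them in reverse). Empty for a single affine layer.
#' @param activation One of \code{"sigmoid"}, \code{"elu"}, \code{"linear"}.
#' @param seed Integer RNG seed for the weight draw.
#' @return An object of class \code{sindy_ae_network} with fields
#'   \code{encoder}, \code{decoder} (lists of \code{W}, \code{b}),
#'   \code{activation}, \code{n}, \code{d}, \code{seed}.
#' @export
init_network <- function(n, d, hidden_widths = integer(0),
                         activation = c("sigmoid", "elu", "linear"),
                         seed = 0L) {
  activation <- match.arg(activation)
  stopifnot(d >= 1, n >= d)
  enc_widths <- c(n, hidden_widths, d)
  dec_widths <- c(d, rev(hidden_widths), n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  make_stack <- function(widths) {
    lapply(seq_len(length(widths) - 1), function(l) {
      fan_in <- widths[l]
      list(W = matrix(stats::rnorm(fan_in * widths[l + 1], sd = 1 / sqrt(fan_in)),
                      fan_in, widths[l + 1]),
           b = rep(0, widths[l + 1]))
    })
  }
  structure(
    list(encoder = make_stack(enc_widths), decoder = make_stack(dec_widths),
         activation = activation, n = as.integer(n), d = as.integer(d),
         hidden_widths = as.integer(hidden_widths), seed = as.integer(seed)),
    class = "sindy_ae_network"
  )
}

#' @export
print.sindy_ae_network <- function(x, ...) {
  widths <- c(x$n, x$hidden_widths, x$d)
  cat(sprintf("<sindy_ae_network> %s (%s), decoder mirrored\n",
              paste(widths, collapse = " -> "), x$activation))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# activation value and its first three derivatives (third needed by the
# backward pass of second-order propagation)
activation_funs <- function(name) {
  switch(
    name,
    sigmoid = list(
      f = function(a) 1 / (1 + exp(-a)),
      f1 = function(a) { s <- 1 / (1 + exp(-a)); s * (1 - s) },
      f2 = function(a) { s <- 1 / (1 + exp(-a)); s * (1 - s) * (1 - 2 * s) },
      f3 = function(a) { s <- 1 / (1 + exp(-a)); s * (1 - s) * (1 - 6 * s + 6 * s^2) },
      order2_ok = TRUE
    ),
    elu = list(
      f = function(a) ifelse(a > 0, a, exp(pmin(a, 0)) - 1),
      f1 = function(a) ifelse(a > 0, 1, exp(pmin(a, 0))),
      f2 = function(a) ifelse(a > 0, 0, exp(pmin(a, 0))),
      f3 = function(a) ifelse(a > 0, 0, exp(pmin(a, 0))),
      order2_ok = FALSE
    ),
    linear = list(
      f = identity, f1 = function(a) a * 0 + 1,
      f2 = function(a) a * 0, f3 = function(a) a * 0,
      order2_ok = TRUE
    ),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_row_matrix <- function(x, width, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != width) {
    stop(sprintf("%s: input has %d columns, expected %d", what, ncol(x), width),
         call. = FALSE)
  }
  x
}

# Forward pass of one stack carrying (value, first, second time derivative).
# dX/ddX may be NULL. Hidden layers activated, last layer affine.
# Returns h/dh/ddh at the output plus per-layer caches for the backward pass.
nn_forward <- function(layers, activation, X, dX = NULL, ddX = NULL) {
  act <- activation_funs(activation)
  L <- length(layers)
  h <- X; dh <- dX; ddh <- ddX
  cache <- vector("list", L)
  for (l in seq_len(L)) {
    W <- layers[[l]]$W; b <- layers[[l]]$b
    a <- sweep(h %*% W, 2, b, "+")
    u <- if (!is.null(dh)) dh %*% W else NULL
    v <- if (!is.null(ddh)) ddh %*% W else NULL
    cache[[l]] <- list(h_in = h, dh_in = dh, ddh_in = ddh, a = a, u = u, v = v)
    if (l == L) {
      h <- a; dh <- u; ddh <- v
    } else {
      f1a <- act$f1(a)
      if (!is.null(ddh)) {
        f2a <- act$f2(a)
        ddh <- f2a * u * u + f1a * v
      }
      if (!is.null(dh)) dh <- f1a * u
      h <- act$f(a)
    }
  }
  list(h = h, dh = dh, ddh = ddh, cache = cache)
}

# Reverse pass matching nn_forward: given gradients of a scalar loss w.r.t.
# the stack outputs (any of Gh/Gdh/Gddh may be NULL = zero), returns per-layer
# parameter gradients and the gradients w.r.t. the stack inputs.
nn_backward <- function(layers, activation, cache, Gh, Gdh = NULL, Gddh = NULL) {
  act <- activation_funs(activation)
  L <- length(layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    cc <- cache[[l]]
    W <- layers[[l]]$W
    if (l == L) {
      Ga <- Gh; Gu <- Gdh; Gv <- Gddh
    } else {
      f1a <- act$f1(cc$a)
      Ga <- if (!is.null(Gh)) Gh * f1a else NULL
      Gu <- if (!is.null(Gdh)) Gdh * f1a else NULL
      Gv <- NULL
      if (!is.null(Gdh) || !is.null(Gddh)) {
        f2a <- act$f2(cc$a)
        if (!is.null(Gdh)) {
          add <- Gdh * f2a * cc$u
          Ga <- if (is.null(Ga)) add else Ga + add
        }
      }
      if (!is.null(Gddh)) {
        f2a <- act$f2(cc$a); f3a <- act$f3(cc$a)
        add <- Gddh * (f3a * cc$u * cc$u + f2a * cc$v)
        Ga <- if (is.null(Ga)) add else Ga + add
        add_u <- Gddh * 2 * f2a * cc$u
        Gu <- if (is.null(Gu)) add_u else Gu + add_u
        Gv <- Gddh * f1a
      }
    }
    GW <- matrix(0, nrow(W), ncol(W))
    Gb <- rep(0, ncol(W))
    if (!is.null(Ga)) {
      GW <- GW + crossprod(cc$h_in, Ga)
      Gb <- Gb + colSums(Ga)
    }
    if (!is.null(Gu)) GW <- GW + crossprod(cc$dh_in, Gu)
    if (!is.null(Gv)) GW <- GW + crossprod(cc$ddh_in, Gv)
    grads[[l]] <- list(W = GW, b = Gb)
    Gh <- if (!is.null(Ga)) Ga %*% t(W) else NULL
    Gdh <- if (!is.null(Gu)) Gu %*% t(W) else NULL
    Gddh <- if (!is.null(Gv)) Gv %*% t(W) else NULL
  }
  list(grads = grads, Gh_in = Gh, Gdh_in = Gdh, Gddh_in = Gddh)
}

#' Encode measurements into latent coordinates
#'
#' Row-wise application of the encoder \eqn{z = \varphi(x)} (or the decoder
#' \eqn{\hat x = \psi(z)} for \code{decode}).
#'
#' @param params A \code{\link{init_network}} object.
#' @param X Matrix with one snapshot per row (a vector is one snapshot).
#' @return Matrix of latent coordinates (resp. reconstructions); a vector if
#'   the input was a vector.
#' @export
encode <- function(params, X) {
  vec <- is.null(dim(X))
  X <- as_row_matrix(X, params$n, "encode")
  Z <- nn_forward(params$encoder, params$activation, X)$h
  if (vec) as.vector(Z) else Z
}

#' @rdname encode
#' @param Z Matrix of latent coordinates, one per row.
#' @export
decode <- function(params, Z) {
  vec <- is.null(dim(Z))
  Z <- as_row_matrix(Z, params$d, "decode")
  Xh <- nn_forward(params$decoder, params$activation, Z)$h
  if (vec) as.vector(Xh) else Xh
}

#' Chain-rule propagation of time derivatives through the encoder
#'
#' Computes \eqn{z = \varphi(x)} and \eqn{\dot z = \nabla_x \varphi(x)\,\dot x}
#' exactly, layer by layer, without materializing the full Jacobian.
#'
#' @param params A \code{\link{init_network}} object.
#' @param x,dx Snapshot(s) and their time derivatives (vectors or matrices of
#'   matching shape).
#' @return List with elements \code{z} and \code{dz}.
#' @export
propagate_dz <- function(params, x, dx) {
  vec <- is.null(dim(x))
  x <- as_row_matrix(x, params$n, "propagate_dz")
  dx <- as_row_matrix(dx, params$n, "propagate_dz")
  stopifnot(nrow(x) == nrow(dx))
  fw <- nn_forward(params$encoder, params$activation, x, dx)
  if (vec) list(z = as.vector(fw$h), dz = as.vector(fw$dh))
  else list(z = fw$h, dz = fw$dh)
}

#' Reconstruct measurement-space derivatives from latent-model velocities
#'
#' Applies the decoder Jacobian action
#' \eqn{\dot{\hat x} = \nabla_z \psi(z)\,\dot z}, the factor used by the
#' derivative-reconstruction loss term.
#'
#' @param params A \code{\link{init_network}} object.
#' @param z Latent coordinates.
#' @param dz_model Latent velocities (typically \eqn{\Theta(z)\Xi}).
#' @return The reconstructed \eqn{\dot x} (same shape convention as inputs).
#' @export
propagate_dx <- function(params, z, dz_model) {
  vec <- is.null(dim(z))
  z <- as_row_matrix(z, params$d, "propagate_dx")
  dz_model <- as_row_matrix(dz_model, params$d, "propagate_dx")
  stopifnot(nrow(z) == nrow(dz_model))
  fw <- nn_forward(params$decoder, params$activation, z, dz_model)
  if (vec) as.vector(fw$dh) else fw$dh
}

check_order2_activation <- function(params) {
  if (!activation_funs(params$activation)$order2_ok) {
    stop(sprintf(
      "activation '%s' is not smooth enough for second-order propagation; use sigmoid or linear",
      params$activation), call. = FALSE)
  }
}

#' Second-order chain-rule propagation through the encoder
#'
#' Computes \eqn{(z, \dot z, \ddot z)} from \eqn{(x, \dot x, \ddot x)} using
#' \eqn{\ddot z = \dot x^\top \nabla^2\varphi\, \dot x + \nabla\varphi\,
#' \ddot x}, propagated layer-wise as (value, first, second) triples. Needed
#' for second-order latent models such as the pendulum.
#'
#' @param params A \code{\link{init_network}} object (activation must be
#'   twice differentiable: sigmoid or linear).
#' @param x,dx,ddx Snapshots and their first and second time derivatives.
#' @return List with elements \code{z}, \code{dz}, \code{ddz}.
#' @export
propagate_second <- function(params, x, dx, ddx) {
  check_order2_activation(params)
  vec <- is.null(dim(x))
  x <- as_row_matrix(x, params$n, "propagate_second")
  dx <- as_row_matrix(dx, params$n, "propagate_second")
  ddx <- as_row_matrix(ddx, params$n, "propagate_second")
  fw <- nn_forward(params$encoder, params$activation, x, dx, ddx)
  if (vec) list(z = as.vector(fw$h), dz = as.vector(fw$dh),
                ddz = as.vector(fw$ddh))
  else list(z = fw$h, dz = fw$dh, ddz = fw$ddh)
}

#' Decoder-side second-order reconstruction
#'
#' Mirror of \code{\link{propagate_second}}: reconstructs \eqn{\ddot{\hat x} =
#' \dot z^\top \nabla^2\psi\, \dot z + \nabla\psi\, \ddot z} from latent
#' position, velocity and (model-predicted) acceleration.
#'
#' @param params A \code{\link{init_network}} object.
#' @param z,dz Latent position and velocity.
#' @param ddz_model Latent acceleration (typically \eqn{\Theta(z,\dot z)\Xi}).
#' @return List with elements \code{xhat}, \code{dx}, \code{ddx}.
#' @export
propagate_ddx <- function(params, z, dz, ddz_model) {
  check_order2_activation(params)
  vec <- is.null(dim(z))
  z <- as_row_matrix(z, params$d, "propagate_ddx")
  dz <- as_row_matrix(dz, params$d, "propagate_ddx")
  ddz_model <- as_row_matrix(ddz_model, params$d, "propagate_ddx")
  fw <- nn_forward(params$decoder, params$activation, z, dz, ddz_model)
  if (vec) list(xhat = as.vector(fw$h), dx = as.vector(fw$dh),
                ddx = as.vector(fw$ddh))
  else list(xhat = fw$h, dx = fw$dh, ddx = fw$ddh)
}
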