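# Independent dense-Jacobian/Hessian oracles used to cross-check the
# layer-wise derivative propagation and the loss terms. Everything here is
# written with explicit per-sample matrices and loops, deliberately not
# sharing code with the package's propagation path.

act_oracle <- function(name) {
  switch(name,
    sigmoid = list(f = function(a) 1 / (1 + exp(-a)),
                   f1 = function(a) exp(-a) / (1 + exp(-a))^2,
                   f2 = function(a) {
                     s <- 1 / (1 + exp(-a)); s * (1 - s) - 2 * s^2 * (1 - s)
                   }),
    elu = list(f = function(a) ifelse(a > 0, a, exp(a) - 1),
               f1 = function(a) ifelse(a > 0, 1, exp(a)),
               f2 = function(a) ifelse(a > 0, 0, exp(a))),
    linear = list(f = identity, f1 = function(a) rep(1, length(a)),
                  f2 = function(a) rep(0, length(a)))
  )
}

# value, dense Jacobian (out x n) and dense Hessian (out x n x n) of one
# network stack at a single input vector
dense_forward <- function(layers, activation, x) {
  acts <- act_oracle(activation)
  n <- length(x)
  h <- x
  J <- diag(n)
  H <- array(0, c(n, n, n))
  L <- length(layers)
  for (l in seq_len(L)) {
    W <- layers[[l]]$W; b <- layers[[l]]$b
    out <- ncol(W)
    a <- as.vector(t(W) %*% h + b)
    Ja <- t(W) %*% J
    Ha <- array(0, c(out, n, n))
    for (o in seq_len(out)) {
      for (i in seq_len(nrow(W))) {
        Ha[o, , ] <- Ha[o, , ] + W[i, o] * H[i, , ]
      }
    }
    if (l == L) {
      h <- a; J <- Ja; H <- Ha
    } else {
      f1 <- acts$f1(a); f2 <- acts$f2(a)
      h <- acts$f(a)
      Jnew <- Ja * f1
      Hnew <- array(0, c(out, n, n))
      for (o in seq_len(out)) {
        Hnew[o, , ] <- f2[o] * outer(Ja[o, ], Ja[o, ]) + f1[o] * Ha[o, , ]
      }
      J <- Jnew; H <- Hnew
    }
  }
  list(h = h, J = J, H = H)
}

# brute-force loss terms via dense Jacobians/Hessians, one sample at a time
dense_loss_terms <- function(params, spec, xi, batch) {
  m <- nrow(batch$X)
  order2 <- spec$model_order == 2
  recon <- sindy_z <- sindy_x <- 0
  for (i in seq_len(m)) {
    x <- batch$X[i, ]; dx <- batch$dX[i, ]
    enc <- dense_forward(params$encoder, params$activation, x)
    z <- enc$h
    dz <- as.vector(enc$J %*% dx)
    if (order2) {
      ddx <- batch$ddX[i, ]
      ddz <- as.vector(enc$J %*% ddx)
      for (o in seq_along(z)) ddz[o] <- ddz[o] + as.numeric(t(dx) %*% enc$H[o, , ] %*% dx)
      theta <- build_library(matrix(c(z, dz), 1), spec)
      pred <- as.vector(theta %*% xi$values)
      dec <- dense_forward(params$decoder, params$activation, z)
      ddx_rec <- as.vector(dec$J %*% pred)
      for (o in seq_along(x)) ddx_rec[o] <- ddx_rec[o] + as.numeric(t(dz) %*% dec$H[o, , ] %*% dz)
      recon <- recon + sum((x - dec$h)^2)
      sindy_z <- sindy_z + sum((ddz - pred)^2)
      sindy_x <- sindy_x + sum((ddx - ddx_rec)^2)
    } else {
      theta <- build_library(matrix(z, 1), spec)
      pred <- as.vector(theta %*% xi$values)
      dec <- dense_forward(params$decoder, params$activation, z)
      dx_rec <- as.vector(dec$J %*% pred)
      recon <- recon + sum((x - dec$h)^2)
      sindy_z <- sindy_z + sum((dz - pred)^2)
      sindy_x <- sindy_x + sum((dx - dx_rec)^2)
    }
  }
  list(recon = recon / m, sindy_z = sindy_z / m, sindy_x = sindy_x / m,
       l1 = sum(abs(xi$values[xi$mask != 0])))
}

# small random coefficient matrix with full mask
random_xi <- function(spec, seed = 1) {
  set.seed(seed)
  p <- library_size(spec)
  d <- spec$latent_dim
  coefficient_matrix(matrix(stats::rnorm(p * d), p, d), matrix(1, p, d),
                     terms = library_terms(spec))
}

# an exactly representable linear system: orthonormal lift V, latent dynamics
# z. = A z, encoder t(V), decoder V, coefficients = A rows in the library
exact_linear_model <- function(n = 4, d = 2, seed = 5) {
  set.seed(seed)
  A <- matrix(c(-0.5, -2, 2, -0.5), 2, 2)
  V <- qr.Q(qr(matrix(stats::rnorm(n * d), n, d)))
  spec <- library_spec(d, poly_order = 2)
  params <- init_network(n, d, integer(0), "linear", seed = seed)
  params$encoder[[1]]$W <- V
  params$encoder[[1]]$b <- rep(0, d)
  params$decoder[[1]]$W <- t(V)
  params$decoder[[1]]$b <- rep(0, n)
  vals <- matrix(0, library_size(spec), d)
  rownames(vals) <- library_terms(spec)
  vals["z1", ] <- A[, 1]
  vals["z2", ] <- A[, 2]
  xi <- coefficient_matrix(vals, terms = library_terms(spec))
  # data generated exactly by this model
  m <- 30
  Z <- matrix(stats::rnorm(m * d), m, d)
  dZ <- Z %*% t(A)
  ds <- snapshot_dataset(Z %*% t(V), dZ %*% t(V))
  list(params = params, spec = spec, xi = xi, dataset = ds, A = A, V = V)
}

# reference support of the toy linear dynamics in an order-2 polynomial
# library over two latent coordinates
linear_toy_support <- function(spec) {
  rs <- matrix(0, library_size(spec), 2)
  rownames(rs) <- library_terms(spec)
  rs["z1", 1] <- rs["z2", 1] <- rs["z1", 2] <- rs["z2", 2] <- 1
  rs != 0
}

# shipped training configuration for the linear toy benchmark
linear_toy_config <- function(seed = 0L, epochs = 2000) {
  training_config(
    epochs = epochs, batch_size = 256, learning_rate = 3e-3,
    threshold = 0.1, threshold_interval = 500, refinement_epochs = 200,
    seed = seed, validation_fraction = 0.2,
    weights = loss_weights(1e-2, 1e-3, 1e-4),
    spec = library_spec(2, poly_order = 2),
    hidden_widths = integer(0), activation = "linear",
    history_interval = 500
  )
}
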