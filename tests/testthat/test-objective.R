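test_that("loss terms match the dense-Jacobian oracle (order 1)", {
  set.seed(20)
  for (act in c("sigmoid", "elu", "linear")) {
    net <- init_network(3, 2, c(4), act, seed = 21)
    spec <- library_spec(2, poly_order = 2, include_sine = TRUE)
    xi <- random_xi(spec, seed = 22)
    ds <- snapshot_dataset(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3))
    got <- loss_terms(net, spec, xi, ds)
    want <- dense_loss_terms(net, spec, xi, ds)
    for (nm in c("recon", "sindy_z", "sindy_x", "l1")) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10)
    }
  }
})

test_that("loss terms match the dense-Jacobian oracle (order 2)", {
  set.seed(23)
  net <- init_network(4, 1, c(5), "sigmoid", seed = 24)
  spec <- library_spec(1, poly_order = 2, include_sine = TRUE,
                       model_order = 2)
  xi <- random_xi(spec, seed = 25)
  ds <- snapshot_dataset(matrix(rnorm(12), 3, 4), matrix(rnorm(12), 3, 4),
                         matrix(rnorm(12), 3, 4))
  got <- loss_terms(net, spec, xi, ds)
  want <- dense_loss_terms(net, spec, xi, ds)
  for (nm in c("recon", "sindy_z", "sindy_x", "l1")) {
    expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10)
  }
})

test_that("an exactly representable linear system is a zero-loss fixed point", {
  mod <- exact_linear_model()
  terms <- loss_terms(mod$params, mod$spec, mod$xi, mod$dataset)
  expect_equal(terms$recon, 0, tolerance = 1e-20)
  expect_equal(terms$sindy_z, 0, tolerance = 1e-20)
  expect_equal(terms$sindy_x, 0, tolerance = 1e-20)
  expect_equal(terms$l1, sum(abs(mod$A)))
})

test_that("l1 counts only mask-active coefficients", {
  spec <- library_spec(1, poly_order = 2)
  vals <- matrix(c(1, -2, 0.5), 3, 1)
  xi <- coefficient_matrix(vals, matrix(1, 3, 1))
  net <- init_network(2, 1, integer(0), "linear", seed = 0)
  ds <- snapshot_dataset(matrix(rnorm(4), 2, 2), matrix(rnorm(4), 2, 2))
  expect_equal(loss_terms(net, spec, xi, ds)$l1, 3.5)
  xi_masked <- coefficient_matrix(vals, matrix(c(1, 0, 1), 3, 1))
  expect_equal(loss_terms(net, spec, xi_masked, ds)$l1, 1.5)
})

test_that("total loss applies the printed weighting", {
  br <- structure(list(recon = 1, sindy_z = 1, sindy_x = 1, l1 = 1),
                  class = "loss_breakdown")
  expect_equal(total_loss(br, loss_weights(2, 3, 4)), 10)
  expect_equal(total_loss(br, loss_weights(0, 0, 0)), 1)
  # lambda1 pairs with the x-derivative term, lambda2 with the z-derivative
  br2 <- structure(list(recon = 0, sindy_z = 5, sindy_x = 7, l1 = 0),
                   class = "loss_breakdown")
  expect_equal(total_loss(br2, loss_weights(lambda1 = 1, lambda2 = 0,
                                            lambda3 = 0)), 7)
  expect_equal(total_loss(br2, loss_weights(lambda1 = 0, lambda2 = 1,
                                            lambda3 = 0)), 5)
})

test_that("loss terms are invariant to batch row order", {
  set.seed(26)
  net <- init_network(3, 2, c(4), "sigmoid", seed = 27)
  spec <- library_spec(2, poly_order = 2)
  xi <- random_xi(spec, seed = 28)
  X <- matrix(rnorm(18), 6, 3); dX <- matrix(rnorm(18), 6, 3)
  perm <- sample(6)
  a <- loss_terms(net, spec, xi, snapshot_dataset(X, dX))
  b <- loss_terms(net, spec, xi,
                  snapshot_dataset(X[perm, ], dX[perm, ]))
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences of the total loss", {
  set.seed(29)
  cases <- list(
    list(net = init_network(4, 2, c(5), "sigmoid", seed = 30),
         spec = library_spec(2, poly_order = 2),
         ds = snapshot_dataset(matrix(rnorm(12), 3, 4),
                               matrix(rnorm(12), 3, 4))),
    list(net = init_network(3, 1, c(4), "sigmoid", seed = 31),
         spec = library_spec(1, poly_order = 2, include_sine = TRUE,
                             model_order = 2),
         ds = snapshot_dataset(matrix(rnorm(9), 3, 3),
                               matrix(rnorm(9), 3, 3),
                               matrix(rnorm(9), 3, 3)))
  )
  w <- loss_weights(0.3, 0.7, 0.2)
  eps <- 1e-6
  for (cs in cases) {
    xi <- random_xi(cs$spec, seed = 32)
    g <- sindyae:::sae_backward(cs$net, cs$spec, xi, cs$ds, w)
    lossf <- function(net, xi) total_loss(loss_terms(net, cs$spec, xi, cs$ds), w)
    # spot-check weights across layers, biases and coefficients
    for (l in seq_along(cs$net$encoder)) {
      W <- cs$net$encoder[[l]]$W
      r <- sample(nrow(W), 1); cc <- sample(ncol(W), 1)
      np <- cs$net; np$encoder[[l]]$W[r, cc] <- W[r, cc] + eps
      nm <- cs$net; nm$encoder[[l]]$W[r, cc] <- W[r, cc] - eps
      fd <- (lossf(np, xi) - lossf(nm, xi)) / (2 * eps)
      expect_equal(unname(g$encoder[[l]]$W[r, cc]), fd, tolerance = 1e-5)
    }
    for (l in seq_along(cs$net$decoder)) {
      W <- cs$net$decoder[[l]]$W
      r <- sample(nrow(W), 1); cc <- sample(ncol(W), 1)
      np <- cs$net; np$decoder[[l]]$W[r, cc] <- W[r, cc] + eps
      nm <- cs$net; nm$decoder[[l]]$W[r, cc] <- W[r, cc] - eps
      fd <- (lossf(np, xi) - lossf(nm, xi)) / (2 * eps)
      expect_equal(unname(g$decoder[[l]]$W[r, cc]), fd, tolerance = 1e-5)
      bp <- cs$net; bp$decoder[[l]]$b[1] <- bp$decoder[[l]]$b[1] + eps
      bm <- cs$net; bm$decoder[[l]]$b[1] <- bm$decoder[[l]]$b[1] - eps
      fdb <- (lossf(bp, xi) - lossf(bm, xi)) / (2 * eps)
      expect_equal(unname(g$decoder[[l]]$b[1]), fdb, tolerance = 1e-5)
    }
    r <- sample(nrow(xi$values), 1)
    xp <- xi; xp$values[r, 1] <- xi$values[r, 1] + eps
    xm <- xi; xm$values[r, 1] <- xi$values[r, 1] - eps
    fdx <- (lossf(cs$net, xp) - lossf(cs$net, xm)) / (2 * eps)
    expect_equal(unname(g$xi[r, 1]), fdx, tolerance = 1e-5)
  }
})
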