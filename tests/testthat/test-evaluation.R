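test_that("relative L2 error behaves as a norm ratio", {
  set.seed(50)
  truth <- matrix(rnorm(20), 4, 5)
  expect_equal(relative_l2(truth, truth), 0)
  expect_equal(relative_l2(truth, 2 * truth), 1.0)
  est <- truth + matrix(rnorm(20, sd = 0.1), 4, 5)
  expect_equal(relative_l2(truth, est),
               sqrt(sum((truth - est)^2)) / sqrt(sum(truth^2)))
  expect_error(relative_l2(matrix(0, 2, 2), matrix(1, 2, 2)), "zero norm")
})

test_that("an exact linear generating model evaluates to zero error", {
  mod <- exact_linear_model()
  # attach trajectory structure so the simulation metric runs
  times <- seq(0, 2, 0.02)
  deriv <- function(t, y, p) list(as.vector(mod$A %*% y))
  sol <- deSolve::ode(c(1, -0.5), times, deriv, parms = NULL, rtol = 1e-10,
                      atol = 1e-12)
  z <- unname(sol[, -1]); dz <- z %*% t(mod$A)
  test <- snapshot_dataset(z %*% t(mod$V), dz %*% t(mod$V), times = times,
                           traj_id = rep(1L, length(times)))
  rep <- evaluate_model(mod, test)
  expect_lt(rep$rel_err_x, 1e-10)
  expect_lt(rep$rel_err_dx, 1e-10)
  expect_lt(rep$rel_err_dz, 1e-10)
  expect_lt(rep$rel_err_z_sim, 1e-6)
  expect_equal(rep$sim_failure_fraction, 0)
  expect_equal(rep$active_terms, 4L)
})

test_that("an all-zero coefficient matrix predicts nothing", {
  mod <- exact_linear_model()
  mod$xi <- coefficient_matrix(matrix(0, library_size(mod$spec), 2))
  test <- mod$dataset
  rep <- evaluate_model(mod, test)
  expect_equal(rep$rel_err_dz, 1.0)
})

test_that("evaluation matches an independently scripted metric computation", {
  set.seed(51)
  net <- init_network(3, 2, c(4), "sigmoid", seed = 52)
  spec <- library_spec(2, poly_order = 2)
  xi <- random_xi(spec, seed = 53)
  X <- matrix(rnorm(15), 5, 3); dX <- matrix(rnorm(15), 5, 3)
  test <- snapshot_dataset(X, dX)
  rep <- evaluate_model(list(params = net, spec = spec, xi = xi), test)
  # scripted recomputation from the primitive operations
  Z <- encode(net, X)
  pr <- propagate_dz(net, X, dX)
  pred <- build_library(Z, spec) %*% xi$values
  expect_equal(rep$rel_err_x,
               sqrt(sum((X - decode(net, Z))^2)) / sqrt(sum(X^2)))
  expect_equal(rep$rel_err_dz,
               sqrt(sum((pr$dz - pred)^2)) / sqrt(sum(pr$dz^2)))
  expect_equal(rep$rel_err_dx,
               sqrt(sum((dX - propagate_dx(net, Z, pred))^2)) /
                 sqrt(sum(dX^2)))
})

test_that("active term counts track the mask", {
  spec <- library_spec(3, poly_order = 3)
  expect_equal(active_term_count(
    coefficient_matrix(matrix(0, library_size(spec), 3))), 0L)
  ref <- lorenz_reference(spec)
  xi <- coefficient_matrix(ref$values)
  expect_equal(active_term_count(xi), 7L)
  # counts are invariant under axis rescaling
  tv <- sindyae:::transform_coefficients(ref$values, spec, c(2, -0.5, 3), 1:3)
  expect_equal(active_term_count(coefficient_matrix(tv)), 7L)
})

test_that("sparsity matching is reflexive and recognizes rescaled models", {
  spec <- library_spec(3, poly_order = 3)
  ref <- lorenz_reference(spec)
  xi <- coefficient_matrix(ref$values)
  ms <- match_sparsity(xi, ref, spec)
  expect_true(ms$identified)
  expect_lt(ms$max_rel_dev, 1e-6)
  # rescale by (-3, -3, 1): same support family, recoverable coefficients
  tv <- sindyae:::transform_coefficients(ref$values, spec, c(-3, -3, 1), 1:3)
  ms2 <- match_sparsity(coefficient_matrix(tv), ref, spec)
  expect_true(ms2$identified)
  expect_lt(ms2$max_rel_dev, 1e-4)
  expect_equal(unname(abs(ms2$transformed)), unname(abs(ref$values)),
               tolerance = 1e-4)
})

test_that("sparsity matching survives random scalings and permutations", {
  set.seed(54)
  spec <- library_spec(3, poly_order = 2)
  ref <- lorenz_reference(spec)
  for (trial in 1:5) {
    a <- runif(3, 0.3, 3) * sample(c(-1, 1), 3, replace = TRUE)
    perm <- sample(3)
    tv <- sindyae:::transform_coefficients(ref$values, spec, a, perm)
    ms <- match_sparsity(coefficient_matrix(tv), ref, spec)
    expect_true(ms$identified)
    expect_lt(ms$max_rel_dev, 1e-3)
  }
})

test_that("an extra active term defeats the match", {
  spec <- library_spec(3, poly_order = 2)
  ref <- lorenz_reference(spec)
  bad <- ref$values
  bad["z2^2", 3] <- 0.7
  ms <- match_sparsity(coefficient_matrix(bad), ref, spec)
  expect_false(ms$identified)
})

test_that("the pendulum identification criterion checks sin z and its coefficient", {
  spec <- library_spec(1, poly_order = 3, include_sine = TRUE,
                       model_order = 2)
  ref <- pendulum_reference(spec)
  good <- matrix(0, library_size(spec), 1)
  rownames(good) <- library_terms(spec)
  good["sin(z1)", 1] <- -1.04
  ms <- match_sparsity(coefficient_matrix(good), ref, spec)
  expect_true(ms$identified)
  expect_lt(ms$max_rel_dev, 0.1)
  # wrong support: linear restoring force instead of the sine
  lin <- matrix(0, library_size(spec), 1)
  rownames(lin) <- library_terms(spec)
  lin["z1", 1] <- -1
  expect_false(match_sparsity(coefficient_matrix(lin), ref, spec)$identified)
})
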