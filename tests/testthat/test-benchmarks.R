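test_that("Lorenz equilibria and origin give zero right-hand side", {
  cfg <- lorenz_config()
  b <- cfg$beta; r <- cfg$rho
  zstar <- c(sqrt(b * (r - 1)), sqrt(b * (r - 1)), r - 1)
  traj <- simulate_lorenz(cfg, zstar, times = seq(0, 1, 0.1))
  expect_lt(max(abs(traj$dz[1, ])), 1e-10)
  traj0 <- simulate_lorenz(cfg, c(0, 0, 0), times = seq(0, 1, 0.1))
  expect_true(all(abs(traj0$z) < 1e-12))
})

test_that("Lorenz flow divergence is -(sigma + 1 + beta) everywhere", {
  cfg <- lorenz_config()
  h <- 1e-6
  set.seed(40)
  for (trial in 1:5) {
    z <- rnorm(3, sd = 10)
    div <- 0
    for (j in 1:3) {
      zp <- z; zp[j] <- z[j] + h
      zm <- z; zm[j] <- z[j] - h
      div <- div +
        (sindyae:::lorenz_deriv(zp, cfg$sigma, cfg$rho, cfg$beta)[j] -
         sindyae:::lorenz_deriv(zm, cfg$sigma, cfg$rho, cfg$beta)[j]) / (2 * h)
    }
    expect_equal(div, -(cfg$sigma + 1 + cfg$beta), tolerance = 1e-5)
  }
})

test_that("Legendre modes are graded and orthonormal on the grid", {
  U <- legendre_modes(128, 6)
  # P0 is constant, positive after normalization
  expect_lt(diff(range(U[, 1])), 1e-12)
  expect_gt(U[1, 1], 0)
  # P1 strictly increasing and antisymmetric about the midpoint
  expect_true(all(diff(U[, 2]) > 0))
  expect_equal(U[, 2], -rev(U[, 2]), tolerance = 1e-12)
  # Gram matrix is the identity
  G <- crossprod(U)
  expect_lt(max(abs(G - diag(6))), 1e-8)
})

test_that("the Lorenz embedding spans six modes with exact derivatives", {
  cfg <- lorenz_config()
  times <- seq(0, 2, by = 0.001)
  traj <- simulate_lorenz(cfg, c(-8, 7, 27), times)
  U <- legendre_modes(cfg$n_grid, 6)
  ds <- embed_lorenz(traj, U)
  expect_equal(ncol(ds$X), 128L)
  # zero trajectory embeds to zero
  tz <- latent_trajectory(times, traj$z * 0, traj$dz * 0)
  expect_true(all(embed_lorenz(tz, U)$X == 0))
  # numerical rank of the snapshot matrix is at most 6
  sv <- svd(ds$X, nu = 0, nv = 0)$d
  expect_lt(sv[7] / sv[1], 1e-10)
  # dX agrees with central finite differences of X at O(dt^2)
  i <- 100
  fd <- (ds$X[i + 1, ] - ds$X[i - 1, ]) / (2 * 0.001)
  expect_lt(sqrt(sum((fd - ds$dX[i, ])^2) / sum(ds$dX[i, ]^2)), 1e-4)
})

test_that("dataset generation is seeded and shaped as configured", {
  cfg <- lorenz_config(n_ics = 2, t_span = 0.5, dt = 0.05, seed = 9)
  a <- generate_lorenz_dataset(cfg)
  b <- generate_lorenz_dataset(cfg)
  expect_identical(a$X, b$X)
  expect_equal(nrow(a$X), 2 * 11)
  expect_equal(ncol(a$X), 128L)
  expect_equal(unique(a$traj_id), 1:2)
  expect_equal(a$metadata$config$sigma, 10)
})

test_that("reaction-only lambda-omega dynamics follow the polar closed form", {
  cfg <- lambda_omega_config(d1 = 0, d2 = 0, beta = 1, grid_size = 8,
                             dt = 0.01, t_span = 5, init = "uniform", r0 = 1)
  ds <- simulate_lambda_omega(cfg)
  u <- ds$X[, 1]; v <- ds$metadata$V[, 1]
  # radius stays on the unit limit cycle
  expect_lt(max(abs(sqrt(u^2 + v^2) - 1)), 1e-10)
  # rotation rate is -beta
  th <- atan2(v, u)
  dth <- diff(th)
  dth <- ifelse(dth < -pi, dth + 2 * pi, ifelse(dth > pi, dth - 2 * pi, dth))
  expect_equal(mean(dth) / cfg$dt, -cfg$beta, tolerance = 1e-8)
  # from r0 = 0.5 the radius converges up to the limit cycle
  cfg2 <- lambda_omega_config(d1 = 0, d2 = 0, beta = 1, grid_size = 4,
                              dt = 0.01, t_span = 20, init = "uniform",
                              r0 = 0.5)
  ds2 <- simulate_lambda_omega(cfg2)
  rT <- sqrt(ds2$X[nrow(ds2$X), 1]^2 + ds2$metadata$V[nrow(ds2$X), 1]^2)
  expect_equal(rT, 1, tolerance = 1e-6)
  # zero field is a fixed point
  cfg0 <- lambda_omega_config(d1 = 0, d2 = 0, grid_size = 4, dt = 0.01,
                              t_span = 1, init = "uniform", r0 = 0)
  expect_true(all(simulate_lambda_omega(cfg0)$X == 0))
})

test_that("the spiral-wave field stays near unit amplitude with consistent derivatives", {
  cfg <- lambda_omega_config(grid_size = 32, dt = 0.02, t_span = 3,
                             t_transient = 2)
  ds <- simulate_lambda_omega(cfg)
  expect_equal(ncol(ds$X), 32L * 32L)
  expect_lt(max(abs(ds$X)), 1 + 0.05)
  i <- 50
  fd <- (ds$X[i + 1, ] - ds$X[i - 1, ]) / (2 * cfg$dt)
  expect_lt(sqrt(sum((fd - ds$dX[i, ])^2) / sum(ds$dX[i, ]^2)), 1e-2)
})

test_that("a pendulum at rest renders identical frames with zero derivatives", {
  cfg <- pendulum_config(image_size = 21, n_ics = 1, t_span = 1, dt = 0.1)
  ang <- sindyae:::simulate_pendulum_angle(0, 0, seq(0, 1, 0.1))
  fr <- sindyae:::render_pendulum_frames(ang$z, ang$dz, ang$ddz, cfg)
  expect_true(all(fr$dX == 0))
  expect_true(all(fr$ddX == 0))
  expect_equal(fr$X[1, ], fr$X[11, ])
})

test_that("rendered pendulum trajectories conserve energy and track the bob", {
  cfg <- pendulum_config(image_size = 51, n_ics = 2, t_span = 2 * pi * 10,
                         dt = 0.05, seed = 1)
  ds <- render_pendulum(cfg)
  expect_equal(ncol(ds$X), 51L * 51L)
  z <- ds$metadata$z; dz <- ds$metadata$dz
  for (i in unique(ds$traj_id)) {
    E <- dz[ds$traj_id == i]^2 / 2 - cos(z[ds$traj_id == i])
    expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-6)
  }
  # image centroid tracks the bob within one pixel
  ax <- seq(-1.5, 1.5, length.out = 51)
  px <- rep(ax, times = 51); py <- rep(ax, each = 51)
  pixel <- ax[2] - ax[1]
  for (row in c(1, 50, 200)) {
    f <- ds$X[row, ]
    cx <- sum(px * f) / sum(f); cy <- sum(py * f) / sum(f)
    expect_lt(abs(cx - sin(z[row])), pixel)
    expect_lt(abs(cy + cos(z[row])), pixel)
  }
  # dX and ddX agree with finite differences over the frame sequence
  idx <- which(ds$traj_id == 1)[10:12]
  fd1 <- (ds$X[idx[3], ] - ds$X[idx[1], ]) / (2 * cfg$dt)
  expect_lt(sqrt(sum((fd1 - ds$dX[idx[2], ])^2) / sum(ds$dX[idx[2], ]^2)),
            0.05)
  fd2 <- (ds$X[idx[3], ] - 2 * ds$X[idx[2], ] + ds$X[idx[1], ]) / cfg$dt^2
  expect_lt(sqrt(sum((fd2 - ds$ddX[idx[2], ])^2) / sum(ds$ddX[idx[2], ]^2)),
            0.05)
})

test_that("sampled pendulum initial conditions stay below the separatrix", {
  cfg <- pendulum_config(n_ics = 30, t_span = 0.1, dt = 0.1, image_size = 11,
                         seed = 3)
  ds <- render_pendulum(cfg)
  first <- !duplicated(ds$traj_id)
  E0 <- ds$metadata$dz[first]^2 / 2 - cos(ds$metadata$z[first])
  expect_true(all(E0 < 0.99))
})
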