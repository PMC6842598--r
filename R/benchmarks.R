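#' Lorenz benchmark configuration
#'
#' Canonical chaotic regime by default: \eqn{\sigma = 10}, \eqn{\rho = 28},
#' \eqn{\beta = 8/3}. The high-dimensional dataset embeds the 3-dimensional
#' trajectories into \code{n_grid = 128} spatial points through six Legendre
#' modes (see \code{\link{embed_lorenz}}).
#'
#' @param sigma,rho,beta Lorenz parameters.
#' @param n_ics Number of training initial conditions.
#' @param t_span Length of each trajectory (time units).
#' @param dt Sampling interval.
#' @param ic_box 3 x 2 matrix of per-coordinate sampling bounds for initial
#'   conditions; default \eqn{[-20, 20]^2 \times [10, 40]}.
#' @param n_grid Spatial grid size of the embedding (128).
#' @param seed RNG seed for IC sampling.
#' @return An object of class \code{lorenz_config}.
#' @export
lorenz_config <- function(sigma = 10, rho = 28, beta = 8 / 3, n_ics = 64,
                          t_span = 5, dt = 0.02,
                          ic_box = rbind(c(-20, 20), c(-20, 20), c(10, 40)),
                          n_grid = 128L, seed = 0L) {
  stopifnot(dt > 0, t_span > dt)
  structure(list(sigma = sigma, rho = rho, beta = beta,
                 n_ics = as.integer(n_ics), t_span = t_span, dt = dt,
                 ic_box = ic_box, n_grid = as.integer(n_grid),
                 seed = as.integer(seed)),
            class = "lorenz_config")
}

lorenz_deriv <- function(z, sigma, rho, beta) {
  c(sigma * (z[2] - z[1]),
    z[1] * (rho - z[3]) - z[2],
    z[1] * z[2] - beta * z[3])
}

#' Simulate the Lorenz system
#'
#' Integrates \eqn{\dot z_1 = \sigma(z_2 - z_1)}, \eqn{\dot z_2 = z_1(\rho -
#' z_3) - z_2}, \eqn{\dot z_3 = z_1 z_2 - \beta z_3} at tight tolerance;
#' the returned velocities are evaluated from the right-hand side, not finite
#' differences.
#'
#' @param config A \code{\link{lorenz_config}}.
#' @param z0 Initial state (length 3).
#' @param times Strictly increasing output times.
#' @param rtol,atol Reference-quality solver tolerances.
#' @return A \code{\link{latent_trajectory}} with d = 3.
#' @export
simulate_lorenz <- function(config, z0, times, rtol = 1e-9, atol = 1e-12) {
  stopifnot(length(z0) == 3, all(diff(times) > 0))
  deriv <- function(t, y, p) list(lorenz_deriv(y, config$sigma, config$rho,
                                               config$beta))
  sol <- deSolve::ode(as.numeric(z0), times, deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(sol) < length(times) || anyNA(sol)) {
    stop("simulate_lorenz: integration failed", call. = FALSE)
  }
  z <- unname(sol[, -1, drop = FALSE])
  dz <- t(apply(z, 1, lorenz_deriv, sigma = config$sigma, rho = config$rho,
                beta = config$beta))
  latent_trajectory(times, z, dz)
}

#' Legendre spatial modes on a uniform grid
#'
#' Column k samples the Legendre polynomial \eqn{P_{k-1}} on \code{n_grid}
#' uniform points over \eqn{[-1, 1]}, then the columns are orthonormalized on
#' the grid (thin QR with positive diagonal, which preserves the graded
#' polynomial structure). Orthonormalization fixes the otherwise arbitrary
#' scaling of the embedding coefficients.
#'
#' @param n_grid Number of grid points (128 for the benchmark).
#' @param n_modes Number of modes (6 for the benchmark); \code{n_modes <=
#'   n_grid}.
#' @return Matrix \eqn{U} of size \code{n_grid x n_modes} with orthonormal
#'   columns.
#' @export
legendre_modes <- function(n_grid = 128L, n_modes = 6L) {
  stopifnot(n_modes <= n_grid, n_modes >= 1)
  x <- seq(-1, 1, length.out = n_grid)
  P <- matrix(0, n_grid, n_modes)
  P[, 1] <- 1
  if (n_modes >= 2) P[, 2] <- x
  if (n_modes >= 3) {
    for (k in 3:n_modes) {  # Bonnet recurrence
      nn <- k - 2
      P[, k] <- ((2 * nn + 1) * x * P[, k - 1] - nn * P[, k - 2]) / (nn + 1)
    }
  }
  qrP <- qr(P)
  Q <- qr.Q(qrP)
  s <- sign(diag(qr.R(qrP)))
  U <- sweep(Q, 2, s, "*")
  colnames(U) <- paste0("u", seq_len(n_modes))
  U
}

#' Embed a Lorenz trajectory into a high-dimensional dataset
#'
#' Builds \eqn{x(t) = u_1 z_1 + u_2 z_2 + u_3 z_3 + u_4 z_1^3 + u_5 z_2^3 +
#' u_6 z_3^3} with exact time derivatives \eqn{\dot x = \sum_i u_i \dot z_i +
#' 3 u_{3+i} z_i^2 \dot z_i}; every row lies in the 6-dimensional span of the
#' modes.
#'
#' @param traj A d = 3 \code{\link{latent_trajectory}} with velocities.
#' @param modes Mode matrix from \code{\link{legendre_modes}} (>= 6 columns).
#' @param traj_id Optional trajectory label to store alongside the rows.
#' @return A \code{\link{snapshot_dataset}} with n = \code{nrow(modes)}.
#' @export
embed_lorenz <- function(traj, modes, traj_id = NULL) {
  stopifnot(ncol(traj$z) == 3, ncol(modes) >= 6)
  U <- modes[, 1:6, drop = FALSE]
  W <- cbind(traj$z, traj$z^3)
  dW <- cbind(traj$dz, 3 * traj$z^2 * traj$dz)
  X <- W %*% t(U)
  dX <- dW %*% t(U)
  id <- if (!is.null(traj_id)) rep(traj_id, nrow(X))
  snapshot_dataset(X, dX, times = traj$times, traj_id = id,
                   metadata = list(generator = "lorenz_embedding"))
}

#' Generate the full high-dimensional Lorenz training dataset
#'
#' Samples \code{n_ics} initial conditions uniformly from \code{ic_box},
#' simulates each at reference tolerance, embeds through the Legendre modes
#' and concatenates, keeping trajectory labels.
#'
#' @param config A \code{\link{lorenz_config}}.
#' @param ic_scale Multiplier on the IC box half-width (use > 1 to sample
#'   outside the training distribution for generalization tests).
#' @return A \code{\link{snapshot_dataset}} with n = \code{config$n_grid}.
#' @export
generate_lorenz_dataset <- function(config, ic_scale = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  modes <- legendre_modes(config$n_grid, 6L)
  times <- seq(0, config$t_span, by = config$dt)
  ctr <- rowMeans(config$ic_box)
  half <- (config$ic_box[, 2] - config$ic_box[, 1]) / 2 * ic_scale
  parts <- vector("list", config$n_ics)
  for (i in seq_len(config$n_ics)) {
    z0 <- ctr + stats::runif(3, -1, 1) * half
    traj <- simulate_lorenz(config, z0, times)
    parts[[i]] <- embed_lorenz(traj, modes, traj_id = i)
  }
  ds <- snapshot_dataset(
    do.call(rbind, lapply(parts, function(p) p$X)),
    do.call(rbind, lapply(parts, function(p) p$dX)),
    times = unlist(lapply(parts, function(p) p$times)),
    traj_id = unlist(lapply(parts, function(p) p$traj_id)),
    metadata = list(generator = "lorenz", config = unclass(config),
                    modes = modes)
  )
  ds
}

#' Reaction--diffusion (lambda--omega) configuration
#'
#' The system \eqn{u_t = (1 - r^2)u + \beta r^2 v + d_1 \nabla^2 u},
#' \eqn{v_t = -\beta r^2 u + (1 - r^2)v + d_2 \nabla^2 v} with
#' \eqn{r^2 = u^2 + v^2}; \eqn{d_1 = d_2 = 0.1}, \eqn{\beta = 1}. The local
#' reaction kinetics have a circular limit cycle of unit amplitude rotating
#' at rate \eqn{-\beta}; with diffusion a spiral wave forms. Solved on a
#' periodic square \eqn{[-L, L]^2}.
#'
#' @param d1,d2 Diffusion coefficients.
#' @param beta Rotation parameter.
#' @param grid_size Points per axis (100 gives n = 1e4 input dimensions).
#' @param L Half-width of the periodic domain.
#' @param dt Snapshot interval (also splitting step).
#' @param t_span Total simulated time.
#' @param t_transient Time discarded before collecting snapshots, letting the
#'   spiral develop.
#' @param init \code{"spiral"} for the standard one-armed spiral initial
#'   condition, \code{"uniform"} for a spatially uniform state of radius
#'   \code{r0} (useful with \code{d1 = d2 = 0} to study the pure reaction
#'   kinetics).
#' @param r0 Initial radius for \code{init = "uniform"}.
#' @param seed RNG seed (kept for interface uniformity; the solver itself is
#'   deterministic).
#' @return An object of class \code{lambda_omega_config}.
#' @export
lambda_omega_config <- function(d1 = 0.1, d2 = 0.1, beta = 1,
                                grid_size = 100L, L = 10, dt = 0.05,
                                t_span = 10, t_transient = 0,
                                init = c("spiral", "uniform"), r0 = 1,
                                seed = 0L) {
  init <- match.arg(init)
  stopifnot(dt > 0, t_span > 0, grid_size >= 4)
  structure(list(d1 = d1, d2 = d2, beta = beta,
                 grid_size = as.integer(grid_size), L = L, dt = dt,
                 t_span = t_span, t_transient = t_transient, init = init,
                 r0 = r0, seed = as.integer(seed)),
            class = "lambda_omega_config")
}

# Exact solution of the reaction kinetics over a step dt, in polar form:
# rdot = r(1 - r^2)  =>  r(t)^2 = r0^2 e^{2t} / (1 + r0^2(e^{2t} - 1))
# thetadot = -beta r^2  =>  theta(t) = theta0 - (beta/2) log(1 + r0^2(e^{2t}-1))
lo_reaction_step <- function(u, v, beta, dt) {
  r2 <- u^2 + v^2
  g <- 1 + r2 * (exp(2 * dt) - 1)
  scale <- exp(dt) / sqrt(g)
  dtheta <- -(beta / 2) * log(g)
  cs <- cos(dtheta); sn <- sin(dtheta)
  list(u = scale * (u * cs - v * sn), v = scale * (u * sn + v * cs))
}

lo_rhs <- function(u, v, cfg, lap_mult) {
  r2 <- u^2 + v^2
  ut <- (1 - r2) * u + cfg$beta * r2 * v
  vt <- -cfg$beta * r2 * u + (1 - r2) * v
  if (cfg$d1 != 0) ut <- ut + cfg$d1 * spectral_lap(u, lap_mult)
  if (cfg$d2 != 0) vt <- vt + cfg$d2 * spectral_lap(v, lap_mult)
  list(ut = ut, vt = vt)
}

spectral_lap <- function(f, lap_mult) {
  Re(fft(fft(f) * lap_mult, inverse = TRUE)) / length(f)
}

#' Simulate the lambda--omega reaction--diffusion system
#'
#' Strang splitting: an exact closed-form step of the reaction kinetics (the
#' radial and angular equations integrate in closed form) sandwiched between
#' exact half-steps of the diffusion operator applied spectrally (FFT on the
#' periodic grid). Emitted time derivatives are evaluated from the governing
#' right-hand side at each snapshot.
#'
#' @param config A \code{\link{lambda_omega_config}}.
#' @return A \code{\link{snapshot_dataset}}: rows are flattened
#'   \eqn{u(x, y, t)} fields (n = \code{grid_size^2}); the v-field snapshots
#'   are retained in \code{metadata$V}.
#' @export
simulate_lambda_omega <- function(config) {
  ng <- config$grid_size
  xg <- seq(-config$L, config$L, length.out = ng + 1)[1:ng]
  if (config$init == "spiral") {
    gx <- matrix(xg, ng, ng)
    gy <- t(gx)
    r <- sqrt(gx^2 + gy^2)
    th <- atan2(gy, gx)
    u <- tanh(r) * cos(th - r)
    v <- tanh(r) * sin(th - r)
  } else {
    u <- matrix(config$r0, ng, ng)
    v <- matrix(0, ng, ng)
  }
  k <- 2 * pi / (2 * config$L) * c(0:(ng / 2), (-ng / 2 + 1):-1)[1:ng]
  k2 <- outer(k^2, k^2, "+")
  lap_mult <- -k2
  half1 <- exp(-config$d1 * k2 * config$dt / 2)
  half2 <- exp(-config$d2 * k2 * config$dt / 2)
  diffuse <- function(f, half) {
    Re(fft(fft(f) * half, inverse = TRUE)) / length(f)
  }
  n_tr <- round(config$t_transient / config$dt)
  n_keep <- round(config$t_span / config$dt) + 1
  X <- matrix(0, n_keep, ng * ng)
  dX <- matrix(0, n_keep, ng * ng)
  V <- matrix(0, n_keep, ng * ng)
  times <- numeric(n_keep)
  kept <- 0
  total_steps <- n_tr + n_keep - 1
  for (step in 0:total_steps) {
    if (step >= n_tr) {
      kept <- kept + 1
      rhs <- lo_rhs(u, v, config, lap_mult)
      X[kept, ] <- as.vector(u)
      dX[kept, ] <- as.vector(rhs$ut)
      V[kept, ] <- as.vector(v)
      times[kept] <- (step - n_tr) * config$dt
      if (kept == n_keep) break
    }
    if (config$d1 != 0) u <- diffuse(u, half1)
    if (config$d2 != 0) v <- diffuse(v, half2)
    st <- lo_reaction_step(u, v, config$beta, config$dt)
    u <- st$u; v <- st$v
    if (config$d1 != 0) u <- diffuse(u, half1)
    if (config$d2 != 0) v <- diffuse(v, half2)
    if (!all(is.finite(u))) {
      stop("simulate_lambda_omega: solution lost stability; reduce dt",
           call. = FALSE)
    }
  }
  snapshot_dataset(X, dX, times = times, traj_id = rep(1L, n_keep),
                   metadata = list(generator = "lambda_omega",
                                   config = unclass(config), V = V))
}

#' Pendulum video configuration
#'
#' The nonlinear pendulum \eqn{\ddot z = -\sin z} rendered as synthetic
#' video: each frame is a 2D Gaussian bump centered at the bob position
#' \eqn{(\sin z, -\cos z)\cdot} \code{arm_length} on an
#' \code{image_size x image_size} pixel grid over \eqn{[-1.5, 1.5]^2}.
#' Initial conditions are rejected unless their energy \eqn{E = \dot z^2/2 -
#' \cos z} is below 0.99 of the separatrix energy, so all sampled motions
#' librate.
#'
#' @param image_size Pixels per axis (51 gives n = 2601).
#' @param gaussian_width Bump standard deviation in pixels.
#' @param arm_length Pendulum arm length in scene units.
#' @param n_ics Number of initial conditions.
#' @param dt Frame interval.
#' @param t_span Clip length per initial condition.
#' @param z_range,dz_range Sampling bounds for \eqn{z_0} and \eqn{\dot z_0}.
#' @param seed RNG seed.
#' @return An object of class \code{pendulum_config}.
#' @export
pendulum_config <- function(image_size = 51L, gaussian_width = 3,
                            arm_length = 1, n_ics = 20, dt = 0.05,
                            t_span = 10, z_range = c(-pi, pi),
                            dz_range = c(-2, 2), seed = 0L) {
  stopifnot(image_size >= 8, gaussian_width > 0, dt > 0)
  structure(list(image_size = as.integer(image_size),
                 gaussian_width = gaussian_width, arm_length = arm_length,
                 n_ics = as.integer(n_ics), dt = dt, t_span = t_span,
                 z_range = z_range, dz_range = dz_range,
                 seed = as.integer(seed)),
            class = "pendulum_config")
}

pendulum_energy <- function(z, dz) dz^2 / 2 - cos(z)

simulate_pendulum_angle <- function(z0, dz0, times, rtol = 1e-10,
                                    atol = 1e-12) {
  deriv <- function(t, y, p) list(c(y[2], -sin(y[1])))
  sol <- deSolve::ode(c(z0, dz0), times, deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  list(z = sol[, 2], dz = sol[, 3], ddz = -sin(sol[, 2]))
}

# Frame, with exact first and second time derivatives via the chain rule.
# F = exp(-((px-cx)^2 + (py-cy)^2) / (2 w^2)), c(z) = arm * (sin z, -cos z).
render_pendulum_frames <- function(z, dz, ddz, cfg) {
  ng <- cfg$image_size
  ax <- seq(-1.5, 1.5, length.out = ng) * cfg$arm_length
  px <- rep(ax, times = ng)     # column-major flattening: x fast, y slow
  py <- rep(ax, each = ng)
  w <- cfg$gaussian_width * (ax[2] - ax[1])
  m <- length(z)
  n <- ng * ng
  X <- matrix(0, m, n); dX <- matrix(0, m, n); ddX <- matrix(0, m, n)
  for (i in seq_len(m)) {
    cx <- cfg$arm_length * sin(z[i]); cy <- -cfg$arm_length * cos(z[i])
    cx1 <- cfg$arm_length * cos(z[i]); cy1 <- cfg$arm_length * sin(z[i])
    cx2 <- -cx; cy2 <- -cy
    ex <- px - cx; ey <- py - cy
    f <- exp(-(ex^2 + ey^2) / (2 * w^2))
    q <- (ex * cx1 + ey * cy1) / w^2            # dF/dz = F q
    qp <- (-cx1^2 + ex * cx2 - cy1^2 + ey * cy2) / w^2
    Fz <- f * q
    Fzz <- f * (q^2 + qp)
    X[i, ] <- f
    dX[i, ] <- Fz * dz[i]
    ddX[i, ] <- Fzz * dz[i]^2 + Fz * ddz[i]
  }
  list(X = X, dX = dX, ddX = ddX)
}

#' Render the synthetic pendulum video dataset
#'
#' Integrates \eqn{\ddot z = -\sin z} for each sampled initial condition at
#' tight tolerance, then renders Gaussian-bump frames whose first and second
#' time derivatives are exact chain-rule derivatives of the frame with
#' respect to \eqn{(z, \dot z, \ddot z)}.
#'
#' @param config A \code{\link{pendulum_config}}.
#' @return A \code{\link{snapshot_dataset}} with \code{ddX}, trajectory
#'   labels, and the sampled angles in \code{metadata} (\code{z}, \code{dz},
#'   \code{ddz}).
#' @export
render_pendulum <- function(config) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  times <- seq(0, config$t_span, by = config$dt)
  sep_energy <- 1  # E at the separatrix (z = pi, dz = 0) with E = dz^2/2 - cos z
  parts <- vector("list", config$n_ics)
  zs <- list()
  for (i in seq_len(config$n_ics)) {
    repeat {
      z0 <- stats::runif(1, config$z_range[1], config$z_range[2])
      dz0 <- stats::runif(1, config$dz_range[1], config$dz_range[2])
      if (pendulum_energy(z0, dz0) < 0.99 * sep_energy) break
    }
    ang <- simulate_pendulum_angle(z0, dz0, times)
    fr <- render_pendulum_frames(ang$z, ang$dz, ang$ddz, config)
    parts[[i]] <- c(fr, list(times = times, id = rep(i, length(times))))
    zs[[i]] <- ang
  }
  snapshot_dataset(
    do.call(rbind, lapply(parts, `[[`, "X")),
    do.call(rbind, lapply(parts, `[[`, "dX")),
    do.call(rbind, lapply(parts, `[[`, "ddX")),
    times = unlist(lapply(parts, `[[`, "times")),
    traj_id = unlist(lapply(parts, `[[`, "id")),
    metadata = list(generator = "pendulum", config = unclass(config),
                    z = unlist(lapply(zs, `[[`, "z")),
                    dz = unlist(lapply(zs, `[[`, "dz")),
                    ddz = unlist(lapply(zs, `[[`, "ddz")))
  )
}
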