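# Synthetic generators emulating the statistical structure of image-tracked
# ant raft data: active Brownian walkers (the free layer), an isotropically
# contracting structural network with bulk exits and edge deposition, and
# directionally biased walkers on a narrow strip.

#' Active-Brownian-particle parameters
#'
#' @param v0 self-propulsion speed, l/s. Default 0.59, the measured mean free
#'   ant walking speed.
#' @param tau_r orientation correlation time, s. Default 34 s, the measured
#'   correlation time implied by the persistence length of free ants.
#' @param n_ants number of walkers.
#' @param t_end duration, s.
#' @param dt sampling/integration step, s. Must satisfy `dt < tau_r`; a
#'   warning is emitted above `tau_r / 10` where heading discretization
#'   starts to bias finite-difference statistics.
#' @param seed integer RNG seed.
#' @param spread side length (l) of the square over which starting positions
#'   are scattered uniformly; 0 starts all walkers at the origin.
#' @return an `abp_params` list.
#' @export
abp_params <- function(v0 = 0.59, tau_r = 34, n_ants = 200, t_end = 60,
                       dt = 1, seed = 1L, spread = 20) {
  if (v0 < 0) stop("v0 must be >= 0")
  if (tau_r <= 0) stop("tau_r must be > 0")
  if (n_ants < 1) stop("n_ants must be >= 1")
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be > 0")
  if (dt >= tau_r) stop("dt >= tau_r: rotational diffusion unresolved")
  if (dt > tau_r / 10) {
    warning("dt > tau_r/10: finite-difference statistics will be biased")
  }
  structure(list(v0 = v0, tau_r = tau_r, n_ants = as.integer(n_ants),
                 t_end = t_end, dt = dt, seed = as.integer(seed),
                 spread = spread),
            class = "abp_params")
}

#' Generate active-Brownian trajectories
#'
#' Each walker moves at constant speed `v0` while its heading angle performs
#' unbiased rotational diffusion with correlation time `tau_r` (Gaussian
#' heading increments of variance `2 dt / tau_r`), on an unbounded plane.
#'
#' @param p an [abp_params()].
#' @return a [trajectory_table()] with `n_ants` ants sampled every `dt`.
#' @examples
#' tr <- gen_abp_trajectories(abp_params(n_ants = 5, t_end = 20, seed = 7))
#' @export
gen_abp_trajectories <- function(p) {
  stopifnot(inherits(p, "abp_params"))
  set.seed(p$seed)
  n_steps <- floor(p$t_end / p$dt)
  n <- p$n_ants
  theta0 <- stats::runif(n, -pi, pi)
  dtheta <- matrix(stats::rnorm(n * n_steps, sd = sqrt(2 * p$dt / p$tau_r)),
                   nrow = n_steps, ncol = n)
  theta <- rbind(theta0, sweep(apply(dtheta, 2, cumsum), 2, theta0, `+`))
  # displacement over each step uses the heading at the start of the step
  step_x <- p$v0 * cos(theta[seq_len(n_steps), , drop = FALSE]) * p$dt
  step_y <- p$v0 * sin(theta[seq_len(n_steps), , drop = FALSE]) * p$dt
  x0 <- stats::runif(n, 0, p$spread)
  y0 <- stats::runif(n, 0, p$spread)
  x <- rbind(x0, sweep(apply(step_x, 2, cumsum), 2, x0, `+`))
  y <- rbind(y0, sweep(apply(step_y, 2, cumsum), 2, y0, `+`))
  ids <- sprintf("ant%04d", seq_len(n))
  df <- data.frame(ant_id = rep(ids, each = n_steps + 1L),
                   frame = rep(0:n_steps, times = n),
                   t = rep((0:n_steps) * p$dt, times = n),
                   x = as.vector(x), y = as.vector(y), layer = "free")
  trajectory_table(df, frame_interval = p$dt)
}

#' Contracting-raft simulation parameters
#'
#' Ground-truth rates for the treadmilling estimators. Defaults are the
#' experimentally reported raft conditions: linear contraction strain rate
#' 1.75% per minute, structural density 2.54 ants per square body length
#' (0.304 ants/mm^2 at l = 2.9 mm) and edge deposition 0.29 events per
#' minute per body length of perimeter.
#'
#' @param eps_dot contraction strain rate, 1/min (> 0 contracts).
#' @param rho_r structural ant density, ants/l^2.
#' @param gamma edge deposition rate, events/min per l of perimeter.
#' @param n_structural0 initial structural ant count.
#' @param anchor planar anchor point (the rod), length-2 numeric.
#' @param t_end,dt duration and frame interval, s.
#' @param seed integer RNG seed.
#' @param edge_band width (l) of the initial outer annulus whose ants are
#'   tracked to define the circumscribed area `A_r`.
#' @return a `raft_sim_params` list.
#' @export
raft_sim_params <- function(eps_dot = 0.0175, rho_r = 2.54, gamma = 0.29,
                            n_structural0 = 1000L, anchor = c(0, 0),
                            t_end = 3600, dt = 15, seed = 1L, edge_band = 1) {
  if (eps_dot < 0) stop("eps_dot must be >= 0")
  if (rho_r <= 0) stop("rho_r must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (n_structural0 < 4) stop("need at least 4 structural ants")
  structure(list(eps_dot = eps_dot, rho_r = rho_r, gamma = gamma,
                 n_structural0 = as.integer(n_structural0), anchor = anchor,
                 t_end = t_end, dt = dt, seed = as.integer(seed),
                 edge_band = edge_band),
            class = "raft_sim_params")
}

#' Generate a contracting, treadmilling raft
#'
#' Structural ants start uniformly in a disc at density `rho_r` around the
#' anchor. Each frame the network is advected by the isotropic contraction
#' field (exact exponential scaling by `exp(-eps_dot dt)`, so estimator
#' tests are not confounded by integrator error); each structural ant exits
#' to the free layer as a Poisson process with rate `2 eps_dot` (the unique
#' choice that conserves `rho_r` as the area shrinks); free ants deposit
#' onto the perimeter as a Poisson process with rate `gamma` per unit
#' perimeter, each deposit appending `1/rho_r` of structural area.
#'
#' Deposition extends the raft: the growth rim is book-kept as newly parked
#' area whose own contraction is neglected over the run (it is second-order
#' in `eps_dot * t` relative to the deposition signal), so the growth-area
#' increments carry the deposition rate undistorted.
#'
#' @param p a [raft_sim_params()].
#' @return list with elements `trajectories` (a [trajectory_table()] of the
#'   contracting network ants, tracked until they exit), `areas` (an
#'   [area_series()]: `A_r` is the area enclosed by the advected material
#'   curve through the initially-outermost tracked ants), `exit_tally`
#'   (data.frame of per-frame exit/deposition events and alive counts) and
#'   `ground_truth` (the generating rates).
#' @export
gen_contracting_raft <- function(p) {
  stopifnot(inherits(p, "raft_sim_params"))
  set.seed(p$seed)
  eps_s <- p$eps_dot / 60          # per second
  gamma_s <- p$gamma / 60
  n0 <- p$n_structural0
  R0 <- sqrt(n0 / (pi * p$rho_r))
  rr <- R0 * sqrt(stats::runif(n0))
  th <- stats::runif(n0, 0, 2 * pi)
  px <- rr * cos(th); py <- rr * sin(th)
  tracked <- which(rr >= R0 - p$edge_band)
  if (length(tracked) < 3L) tracked <- order(rr, decreasing = TRUE)[1:3]

  n_frames <- floor(p$t_end / p$dt)
  shrink <- exp(-eps_s * p$dt)
  p_exit <- 1 - exp(-2 * eps_s * p$dt)

  alive <- rep(TRUE, n0)
  # the tracked edge ants trace the initial raft perimeter, so the material
  # curve they define starts at the full disc area
  A_core0 <- pi * R0^2
  A_r0 <- A_core0
  A_g <- 0

  traj_chunks <- vector("list", n_frames + 1L)
  area_t <- numeric(n_frames + 1L); area_Ar <- numeric(n_frames + 1L)
  area_A <- numeric(n_frames + 1L); area_Ag <- numeric(n_frames + 1L)
  area_P <- numeric(n_frames + 1L)
  exits <- integer(n_frames + 1L); alive_n <- integer(n_frames + 1L)
  deposits <- integer(n_frames + 1L)

  for (k in 0:n_frames) {
    t_now <- k * p$dt
    A_core <- A_core0 * exp(-2 * eps_s * t_now)
    if (k > 0L) {
      # advect, then exits, then deposition
      px[alive] <- px[alive] * shrink
      py[alive] <- py[alive] * shrink
      ex <- alive & (stats::runif(n0) < p_exit)
      exits[k + 1L] <- sum(ex)
      alive[ex] <- FALSE
      P_now <- 2 * sqrt(pi * (A_core + A_g))
      n_dep <- stats::rpois(1L, gamma_s * P_now * p$dt)
      deposits[k + 1L] <- n_dep
      A_g <- A_g + n_dep / p$rho_r
    }
    alive_n[k + 1L] <- sum(alive)
    area_t[k + 1L] <- t_now
    # material curve through the tracked edge ants, advected exactly
    area_Ar[k + 1L] <- A_r0 * exp(-2 * eps_s * t_now)
    area_A[k + 1L] <- A_core + A_g
    area_Ag[k + 1L] <- area_A[k + 1L] - area_Ar[k + 1L]
    area_P[k + 1L] <- 2 * sqrt(pi * area_A[k + 1L])
    live <- which(alive)
    traj_chunks[[k + 1L]] <- data.frame(
      ant_id = sprintf("str%05d", live),
      frame = k, t = t_now,
      x = px[live] + p$anchor[1],
      y = py[live] + p$anchor[2],
      layer = "structural")
  }

  traj <- do.call(rbind, traj_chunks)
  truncated <- FALSE
  if (any(area_A <= 0)) {
    warning("raft area reached zero before t_end; series truncated")
    truncated <- TRUE
    keep <- area_A > 0
    area_t <- area_t[keep]; area_Ar <- area_Ar[keep]; area_A <- area_A[keep]
    area_Ag <- area_Ag[keep]; area_P <- area_P[keep]
  }
  list(trajectories = trajectory_table(traj, frame_interval = p$dt),
       areas = area_series(area_t, area_Ar, area_A, area_P, A_g = area_Ag),
       exit_tally = data.frame(t = (0:n_frames) * p$dt, exits = exits,
                               deposits = deposits, n_alive = alive_n),
       ground_truth = list(eps_dot = p$eps_dot, rho_r = p$rho_r,
                           gamma = p$gamma, delta_per_ant = 2 * p$eps_dot,
                           anchor = p$anchor, truncated = truncated))
}

#' Generate directionally biased walkers on a strip
#'
#' Active-Brownian dynamics plus a uniform drift of magnitude `bias_speed`
#' along the strip axis (+x); walkers are confined to `|y| <= width/2` by
#' reflection. Used to probe directional-correlation and metric-tensor
#' statistics on biased ensembles resembling ants on a protrusion.
#'
#' @param width strip width, l (> 0).
#' @param length strip length, l; starting x positions are uniform on it.
#' @param bias_speed drift speed along +x, l/s (>= 0).
#' @param p an [abp_params()] supplying `v0`, `tau_r`, `n_ants`, `t_end`,
#'   `dt`, `seed`.
#' @return a [trajectory_table()].
#' @export
gen_strip_walkers <- function(width, length, bias_speed, p) {
  stopifnot(inherits(p, "abp_params"))
  if (width <= 0) stop("width must be > 0")
  if (bias_speed < 0) stop("bias_speed must be >= 0")
  if (width <= (p$v0 + bias_speed) * p$dt) {
    stop("strip width must exceed the per-frame step length")
  }
  set.seed(p$seed)
  n_steps <- floor(p$t_end / p$dt)
  n <- p$n_ants
  theta <- stats::runif(n, -pi, pi)
  x <- stats::runif(n, 0, length)
  y <- stats::runif(n, -width / 2, width / 2)
  X <- matrix(NA_real_, n_steps + 1L, n); Y <- X
  X[1L, ] <- x; Y[1L, ] <- y
  half <- width / 2
  for (k in seq_len(n_steps)) {
    x <- x + (p$v0 * cos(theta) + bias_speed) * p$dt
    y <- y + p$v0 * sin(theta) * p$dt
    over <- y > half
    y[over] <- 2 * half - y[over]; theta[over] <- -theta[over]
    under <- y < -half
    y[under] <- -2 * half - y[under]; theta[under] <- -theta[under]
    theta <- theta + stats::rnorm(n, sd = sqrt(2 * p$dt / p$tau_r))
    X[k + 1L, ] <- x; Y[k + 1L, ] <- y
  }
  ids <- sprintf("ant%04d", seq_len(n))
  df <- data.frame(ant_id = rep(ids, each = n_steps + 1L),
                   frame = rep(0:n_steps, times = n),
                   t = rep((0:n_steps) * p$dt, times = n),
                   x = as.vector(X), y = as.vector(Y), layer = "free")
  trajectory_table(df, frame_interval = p$dt)
}
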