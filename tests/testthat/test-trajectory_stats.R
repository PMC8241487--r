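test_that("finite-difference velocities reproduce hand values", {
  tr <- make_traj(data.frame(x = c(0, 0.59, 1.18), y = c(0, 0, 0)),
                  data.frame(x = rep(2, 3), y = rep(2, 3)))
  vel <- compute_velocities(tr)
  a1 <- vel[vel$ant_id == "a1", ]
  expect_equal(a1$speed, c(0.59, 0.59))
  expect_equal(a1$ux, c(1, 1))
  a2 <- vel[vel$ant_id == "a2", ]
  expect_equal(a2$speed, c(0, 0))
  expect_true(all(is.na(a2$ux)))   # stationary: no direction
  expect_equal(attr(vel, "mean_speed"), mean(c(0.59, 0.59, 0, 0)))

  # a frame gap yields no velocity across the gap
  gap <- trajectory_table(data.frame(ant_id = "g", frame = c(0, 1, 3, 4),
                                     t = c(0, 1, 3, 4), x = c(0, 1, 5, 6),
                                     y = 0), frame_interval = 1)
  vg <- compute_velocities(gap)
  expect_equal(nrow(vg), 2L)
  expect_equal(vg$frame, c(0L, 3L))

  # frame_gap spans multiple frames
  v2 <- compute_velocities(tr, frame_gap = 2L)
  expect_equal(v2[v2$ant_id == "a1", "speed"], 0.59)
})

test_that("every statistic matches its brute-force oracle on small tables", {
  set.seed(101)
  tr <- make_traj(random_ant(10), random_ant(8), random_ant(10),
                  random_ant(6), random_ant(9))

  # velocities
  vel <- compute_velocities(tr)
  bf <- bf_velocities(tr)
  expect_equal(vel$vx, bf$vx, tolerance = 1e-12)
  expect_equal(vel$vy, bf$vy, tolerance = 1e-12)

  # MSD with overlapping starts
  m <- msd_analysis(tr, max_lag = 6, min_duration = 0)
  bm <- bf_msd(tr, 6)
  expect_equal(m$msd, bm$msd[bm$n > 0], tolerance = 1e-10)
  expect_equal(m$n_obs, bm$n[bm$n > 0])

  # metric tensor
  g <- velocity_metric_tensor(vel)
  expect_equal(g$g, bf_metric_tensor(tr), tolerance = 1e-10)

  # pairwise correlation, mixed-time separation, both tau = 0 and 1
  for (tau in c(0, 1)) {
    pc <- pair_correlation(tr, tau_values = tau, bin_width = 0.5,
                           max_sigma = 10)
    bp <- bf_pair_dots(tr, tau)
    bp <- bp[bp$sigma <= 10, ]
    b <- pmin(pmax(ceiling(bp$sigma / 0.5), 1L), 20L)
    for (bin in sort(unique(b))) {
      expect_equal(pc$c[bin], mean(bp$dot[b == bin]), tolerance = 1e-10)
    }
    expect_equal(attr(pc, "summary")$mean_c, mean(bp$dot), tolerance = 1e-10)
  }

  # same-time separation variant
  pcs <- pair_correlation(tr, tau_values = 1, bin_width = 0.5, max_sigma = 10,
                          same_time = TRUE)
  bps <- bf_pair_dots(tr, 1, same_time = TRUE)
  expect_equal(attr(pcs, "summary")$mean_c, mean(bps$dot), tolerance = 1e-10)

  # polar order parameter per domain size
  for (L in c(1, 3, 8)) {
    sc <- order_parameter_scan(tr, L)
    expect_equal(sc$phi_abs, bf_order_param(tr, L), tolerance = 1e-10)
  }
})

test_that("MSD fits recover ballistic and diffusive laws", {
  # straight-line walker: msd = (v tau)^2, xi = 2, 4D = v^2
  tr <- make_traj(straight_ant(40, v = 0.7))
  m <- msd_analysis(tr, max_lag = 10, min_duration = 0)
  expect_equal(m$msd, (0.7 * m$tau)^2, tolerance = 1e-10)
  expect_equal(attr(m, "xi"), 2, tolerance = 1e-8)
  expect_equal(4 * attr(m, "D"), 0.7^2, tolerance = 1e-6)

  # ideal diffusive ensemble generated directly from Gaussian steps
  set.seed(7)
  D <- 0.1
  ants <- lapply(1:200, function(i)
    data.frame(x = cumsum(c(0, stats::rnorm(60, sd = sqrt(2 * D)))),
               y = cumsum(c(0, stats::rnorm(60, sd = sqrt(2 * D))))))
  tr <- do.call(make_traj, ants)
  m <- msd_analysis(tr, max_lag = 15, min_duration = 0)
  expect_lt(abs(attr(m, "xi") - 1), 0.05)
  expect_lt(abs(attr(m, "D") / D - 1), 0.1)

  expect_error(msd_analysis(make_traj(straight_ant(3)), max_lag = 1,
                            min_duration = 0), "3")
})

test_that("polar order is 1 for aligned motion and decays for isotropic", {
  aligned <- make_traj(straight_ant(6, x0 = 0), straight_ant(6, x0 = 0.3),
                       straight_ant(6, y0 = 0.5), straight_ant(6, y0 = 0.9))
  sc <- order_parameter_scan(aligned, c(0.6, 2, 10))
  expect_equal(sc$phi_abs, rep(1, 3), tolerance = 1e-12)

  set.seed(21)
  iso <- gen_abp_trajectories(abp_params(v0 = 1, tau_r = 5, n_ants = 300,
                                         t_end = 5, dt = 0.5, seed = 3,
                                         spread = 10))
  sc <- order_parameter_scan(iso, c(2, 10))
  # ~n^(-1/2) decay: larger domains hold more ants, hence lower order
  expect_lt(sc$phi_abs[2], sc$phi_abs[1])
  expect_lt(sc$phi_abs[2], 0.5)
})

test_that("persistence length flags straight paths and fits known decay", {
  straight <- do.call(make_traj, lapply(1:5, function(i)
    straight_ant(30, v = 0.5, angle = i, x0 = i)))
  fit <- persistence_length(straight, min_travel = 5, mode = "pooled")
  expect_true(fit$saturated)
  expect_identical(fit$l_p, Inf)
  expect_true(all(abs(fit$curve$corr[fit$curve$n_obs > 0] - 1) < 1e-9))

  # ABP with known l_p = v0 tau_r
  p <- abp_params(v0 = 0.59, tau_r = 29.3, n_ants = 105, t_end = 180,
                  dt = 2, seed = 31)
  tr <- gen_abp_trajectories(p)
  fit <- persistence_length(tr, min_travel = 5, bin_width = 1, max_lc = 40,
                            mode = "pooled")
  expect_lt(abs(fit$l_p / (0.59 * 29.3) - 1), 0.2)
  expect_equal(fit$n_ants, 105L)
  # the implied correlation time l_p / v0 lands near tau_r
  expect_lt(abs(fit$l_p / 0.59 - 29.3) / 29.3, 0.2)
})

test_that("parameter recovery holds over a (v0, tau_r) grid", {
  cases <- expand.grid(v0 = c(0.3, 0.59, 1.0), tau_r = c(15, 30, 60))
  for (i in seq_len(nrow(cases))) {
    v0 <- cases$v0[i]; tau_r <- cases$tau_r[i]
    p <- abp_params(v0 = v0, tau_r = tau_r, n_ants = 200,
                    t_end = 8 * tau_r, dt = tau_r / 15, seed = 100 + i)
    tr <- gen_abp_trajectories(p)
    vel <- compute_velocities(tr)
    expect_lt(abs(attr(vel, "mean_speed") / v0 - 1), 0.05)
    fit <- persistence_length(tr, min_travel = 5, bin_width = v0 * tau_r / 15,
                              max_lc = 2.5 * v0 * tau_r, mode = "pooled")
    expect_lt(abs(fit$l_p / (v0 * tau_r) - 1), 0.25)
  }
})

test_that("pair correlation detects co-movement and isotropic nulls", {
  co <- make_traj(straight_ant(8, v = 1, x0 = 0), straight_ant(8, v = 1, y0 = 2),
                  straight_ant(8, v = 1, y0 = 5))
  pc <- pair_correlation(co, tau_values = c(0, 1), bin_width = 1, max_sigma = 10)
  expect_true(all(abs(pc$c[is.finite(pc$c)] - 1) < 1e-12))

  # null ensemble: tracks short relative to the spread, so that conditioning
  # on separation does not itself induce correlation; envelope set by
  # n_ants x frames (pairs sharing an ant are correlated)
  iso <- gen_abp_trajectories(abp_params(v0 = 1, tau_r = 10, n_ants = 300,
                                         t_end = 6, dt = 1, seed = 17,
                                         spread = 40))
  pc <- pair_correlation(iso, tau_values = 0, bin_width = 1, max_sigma = 15)
  ok <- pc$n_pairs > 500
  expect_lt(abs(attr(pc, "summary")$mean_c), 0.05)
  expect_lt(max(abs(pc$c[ok])), 0.15)

  # empty bins are missing, never zero
  expect_true(anyNA(pair_correlation(co, tau_values = 0, bin_width = 0.1,
                                     max_sigma = 10)$c))
})

test_that("the metric tensor has unit trace and oriented principal axes", {
  xward <- make_traj(straight_ant(5), straight_ant(5, y0 = 1))
  g <- velocity_metric_tensor(compute_velocities(xward))
  expect_equal(g$g, diag(c(1, 0)), tolerance = 1e-12)
  expect_equal(g$g1, c(1, 0), tolerance = 1e-12)
  expect_equal(g$g2, c(0, 1), tolerance = 1e-12)  # right-handed

  # anisotropic ensemble built to have diag (0.66, 0.34): closed-form 2x2
  # eigenvalues must match to float precision and sum to 1
  alpha <- acos(sqrt(0.66))
  delta <- 0.0157
  ang <- c(alpha, -alpha) + delta
  g <- velocity_metric_tensor(cbind(cos(ang), sin(ang)))
  ev_closed <- 0.5 + c(1, -1) *
    sqrt(((g$g[1, 1] - g$g[2, 2]) / 2)^2 + g$g[1, 2]^2)
  expect_equal(g$eigenvalues, ev_closed, tolerance = 1e-12)
  expect_equal(sum(g$eigenvalues), 1, tolerance = 1e-12)
  expect_equal(round(g$eigenvalues, 2), c(0.66, 0.34))
  expect_gt(sum(g$g1 * c(1, 0)), 0)   # sense follows net displacement

  expect_error(velocity_metric_tensor(cbind(0, 0)), "positive speed")
})

test_that("trace is exactly unity across random ensembles", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    g <- velocity_metric_tensor(matrix(stats::rnorm(2 * n), ncol = 2))
    expect_lt(abs(sum(diag(g$g)) - 1), 1e-12)
    expect_true(all(g$eigenvalues >= -1e-12 & g$eigenvalues <= 1 + 1e-12))
  }
})

test_that("edge-encountering ants are excluded by a polygon mask", {
  inside <- straight_ant(12, v = 0.6, angle = 0.3, x0 = 10, y0 = 10)
  outside <- straight_ant(12, v = 1.5, angle = 0, x0 = 10, y0 = 1)
  tr <- make_traj(inside, outside)
  mask <- data.frame(x = c(0, 30, 30, 0), y = c(0, 0, 30, 30))
  fit <- persistence_length(tr, min_travel = 3, mode = "per_ant",
                            mask = mask, margin = 2)
  expect_identical(fit$per_ant$ant_id, "a1")
})
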