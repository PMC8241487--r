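test_that("packing fraction follows its defining identity", {
  expect_equal(packing_fraction(100, A = 50, rho_r = 2), 0)
  expect_equal(packing_fraction(200, A = 50, rho_r = 2), 1)
  expect_equal(packing_fraction(1.56 * 100, A = 50, rho_r = 2), 0.56)
  expect_error(packing_fraction(10, A = 0, rho_r = 2), "positive")
  expect_warning(packing_fraction(50, A = 50, rho_r = 2), "below")
})

test_that("areal decay fit is exact on noiseless exponentials", {
  t <- seq(0, 3000, by = 30)
  s <- area_series(t, A_r = 400 * exp(-2 * 0.0175 * t / 60),
                   A = 400 * exp(-2 * 0.0175 * t / 60) + 1,
                   P = rep(70, length(t)))
  fit <- fit_area_decay(s)
  expect_lt(abs(fit$eps_dot - 0.0175), 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  nls_fit <- fit_area_decay(s, method = "nls")
  expect_lt(abs(nls_fit$eps_dot - 0.0175), 1e-7)

  const <- area_series(t, A_r = rep(100, length(t)), A = rep(101, length(t)),
                       P = rep(40, length(t)))
  cfit <- fit_area_decay(const)
  expect_equal(cfit$eps_dot, 0)
  expect_true(is.na(cfit$r_squared))

  grow <- area_series(t[1:10], A_r = 100 * exp(0.001 * t[1:10]),
                      A = 100 * exp(0.001 * t[1:10]), P = rep(40, 10))
  expect_warning(fit_area_decay(grow), "growing")
  expect_error(fit_area_decay(s[1:2, ]), "3 time points")
})

test_that("radial strain fit recovers slope, ignores rotation, handles noise", {
  R <- seq(2, 40, length.out = 60)
  fit <- fit_radial_strain(data.frame(R = R, R_dot = 0.0182 * R))
  expect_equal(fit$eps_dot, 0.0182, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)

  rot <- fit_radial_strain(data.frame(R = R, R_dot = 0 * R))
  expect_equal(rot$eps_dot, 0, tolerance = 1e-12)

  set.seed(5)
  reps <- replicate(50, {
    f <- fit_radial_strain(data.frame(
      R = R, R_dot = 0.0175 * R * (1 + stats::rnorm(60, sd = 0.1))))
    c(f$eps_dot, f$eps_dot_se)
  })
  # estimates scatter consistently with their reported standard errors
  expect_lt(abs(mean(reps[1, ]) - 0.0175), 2 * stats::sd(reps[1, ]) / sqrt(50))
  expect_lt(abs(stats::sd(reps[1, ]) / mean(reps[2, ]) - 1), 0.5)

  expect_error(fit_radial_strain(data.frame(R = c(1, 1, 1), R_dot = 1:3)),
               "distinct R")
})

test_that("exit rate identities and sign convention hold", {
  er <- exit_rate(0.0175, rho_r = 2.54)
  expect_equal(er$delta_per_ant, 0.035)
  expect_equal(er$delta_area, 2 * 2.54 * 0.0175)
  expect_equal(er$delta_area / er$delta_per_ant, 2.54)
  expect_equal(exit_rate(0, 1)$delta_area, 0)
})

test_that("edge deposition recovers constructed and simulated rates", {
  # constructed circular raft with exact gamma = 0.29 events/min/l
  t <- seq(0, 1200, by = 30)
  A0 <- 400; rho_r <- 2.54; gamma <- 0.29
  P <- 2 * sqrt(pi * A0)
  A_g <- gamma * P / rho_r * t / 60
  s <- area_series(t, A_r = rep(A0, length(t)), A = A0 + A_g,
                   P = rep(P, length(t)), A_g = A_g)
  dep <- suppressWarnings(edge_deposition_rate(s, rho_r))
  # P held at its initial value in both construction and series: exact
  expect_lt(abs(dep$gamma - gamma), 0.02 * gamma)
  expect_equal(dep$alpha_area, mean(gamma * P / ((s$A[-1] + s$A[-41]) / 2)),
               tolerance = 0.02)
  expect_equal(dep$alpha_per_ant, dep$alpha_area / rho_r)

  zero <- area_series(t, A_r = rep(A0, length(t)), A = rep(A0, length(t)),
                      P = rep(P, length(t)))
  expect_equal(edge_deposition_rate(zero, rho_r)$gamma, 0)

  # simulated treadmilling raft: gamma and eps within 5%, delta vs 2 eps
  p <- raft_sim_params(seed = 1)
  sim <- gen_contracting_raft(p)
  expect_lt(abs(fit_area_decay(sim$areas)$eps_dot / p$eps_dot - 1), 0.05)
  dep <- suppressWarnings(edge_deposition_rate(sim$areas, p$rho_r))
  expect_lt(abs(dep$gamma / p$gamma - 1), 0.05)
})

test_that("areal and radial strain estimates agree on simulated rafts", {
  p <- raft_sim_params(n_structural0 = 800, t_end = 1800, seed = 4)
  sim <- gen_contracting_raft(p)
  e1 <- fit_area_decay(sim$areas)$eps_dot
  e2 <- fit_radial_strain(radial_field(sim$trajectories, p$anchor))$eps_dot
  expect_lt(abs(e1 / e2 - 1), 0.05)
})

test_that("protrusion metrics return exact geometry and worked rates", {
  n <- 11
  t <- seq(0, 600, by = 60)
  static_tip <- data.frame(t = t, x = 0, y = rep(20, n))
  flanks <- list(data.frame(t = t, x = -3, y = 10),
                 data.frame(t = t, x = 3, y = 10))
  rect <- data.frame(x = c(-3, 3, 3, -3), y = c(0, 0, 20, 20))  # 6 x 20
  pt <- protrusion_metrics(static_tip, flanks, rect)
  expect_true(all(pt$V[-1] == 0))
  expect_equal(pt$W, rep(6, n), tolerance = 1e-12)
  expect_equal(pt$L_c, rep(20, n), tolerance = 1e-12)

  # tip advancing at 0.74 l/min on a 5.85 l wide protrusion reproduces the
  # observed areal tip growth rate and per-edge-length deposition
  tip <- data.frame(t = t, x = 0, y = 20 + 0.74 * t / 60)
  out <- lapply(seq_len(n), function(i)
    data.frame(x = c(-5.85, 5.85, 5.85, -5.85) / 2,
               y = c(0, 0, tip$y[i], tip$y[i])))
  pt <- protrusion_metrics(tip, flanks, out)
  expect_equal(attr(pt, "mean_V"), 0.74, tolerance = 1e-9)
  expect_equal(attr(pt, "mean_W"), 5.85, tolerance = 1e-9)
  areal_rate <- attr(pt, "mean_V") * attr(pt, "mean_W")
  expect_equal(round(areal_rate, 2), 4.33)
  ants_per_min <- areal_rate * 2.54              # ~11 ants/min at rho_r
  gamma_tip <- ants_per_min / attr(pt, "mean_W")
  expect_equal(round(gamma_tip, 1), 1.9)

  expect_error(protrusion_metrics(static_tip,
                                  list(flanks[[1]], flanks[[1]]), rect),
               "coincide")
})

test_that("density conversion bridges mm^-2 and body-length units", {
  expect_equal(density_mm2_to_ell2(0.304, ell_mm = 2.9), 0.304 * 2.9^2)
  expect_lt(abs(density_mm2_to_ell2(0.304) - 2.56), 0.01)
  expect_error(density_mm2_to_ell2(1, ell_mm = 0), "ell_mm")
})
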