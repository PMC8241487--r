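# Code-built fixtures and independent brute-force reference implementations
# (plain double loops) used as oracles for the vectorized statistics.

make_traj <- function(..., dt = 1) {
  ants <- list(...)
  df <- do.call(rbind, lapply(seq_along(ants), function(i) {
    a <- ants[[i]]
    data.frame(ant_id = sprintf("a%d", i), frame = seq_len(nrow(a)) - 1L,
               t = (seq_len(nrow(a)) - 1L) * dt, x = a$x, y = a$y)
  }))
  trajectory_table(df, frame_interval = dt)
}

straight_ant <- function(n, v = 1, angle = 0, dt = 1, x0 = 0, y0 = 0) {
  data.frame(x = x0 + v * cos(angle) * (0:(n - 1)) * dt,
             y = y0 + v * sin(angle) * (0:(n - 1)) * dt)
}

random_ant <- function(n, step = 0.5) {
  data.frame(x = cumsum(c(0, stats::rnorm(n - 1, sd = step))),
             y = cumsum(c(0, stats::rnorm(n - 1, sd = step))))
}

# one velocity record per (ant, frame) with a following frame
bf_velocities <- function(traj) {
  dt <- attr(traj, "frame_interval")
  out <- NULL
  for (a in unique(traj$ant_id)) {
    sub <- traj[traj$ant_id == a, ]
    for (r in seq_len(nrow(sub))) {
      nxt <- which(sub$frame == sub$frame[r] + 1L)
      if (!length(nxt)) next
      vx <- (sub$x[nxt] - sub$x[r]) / dt
      vy <- (sub$y[nxt] - sub$y[r]) / dt
      out <- rbind(out, data.frame(ant_id = a, frame = sub$frame[r],
                                   x = sub$x[r], y = sub$y[r],
                                   vx = vx, vy = vy,
                                   speed = sqrt(vx^2 + vy^2)))
    }
  }
  out
}

bf_msd <- function(traj, kmax, min_duration = 0) {
  dt <- attr(traj, "frame_interval")
  ss <- numeric(kmax); nn <- numeric(kmax)
  for (a in unique(traj$ant_id)) {
    sub <- traj[traj$ant_id == a, ]
    if (max(sub$t) - min(sub$t) < min_duration) next
    for (k in seq_len(kmax)) {
      for (r in seq_len(nrow(sub))) {
        j <- which(sub$frame == sub$frame[r] + k)
        if (!length(j)) next
        ss[k] <- ss[k] + (sub$x[j] - sub$x[r])^2 + (sub$y[j] - sub$y[r])^2
        nn[k] <- nn[k] + 1
      }
    }
  }
  data.frame(tau = seq_len(kmax) * dt, msd = ifelse(nn > 0, ss / nn, NA), n = nn)
}

bf_pair_dots <- function(traj, tau, same_time = FALSE) {
  vel <- bf_velocities(traj)
  dt <- attr(traj, "frame_interval")
  k <- round(tau / dt)
  sig <- c(); dots <- c()
  for (r1 in seq_len(nrow(vel))) {
    for (r2 in seq_len(nrow(vel))) {
      if (vel$ant_id[r1] == vel$ant_id[r2]) next
      if (vel$frame[r2] != vel$frame[r1] + k) next
      if (vel$speed[r1] == 0 || vel$speed[r2] == 0) next
      if (same_time) {
        rj <- which(vel$ant_id == vel$ant_id[r2] & vel$frame == vel$frame[r1])
        if (!length(rj)) next
        s <- sqrt((vel$x[r1] - vel$x[rj])^2 + (vel$y[r1] - vel$y[rj])^2)
      } else {
        s <- sqrt((vel$x[r1] - vel$x[r2])^2 + (vel$y[r1] - vel$y[r2])^2)
      }
      d <- (vel$vx[r1] * vel$vx[r2] + vel$vy[r1] * vel$vy[r2]) /
        (vel$speed[r1] * vel$speed[r2])
      sig <- c(sig, s); dots <- c(dots, d)
    }
  }
  data.frame(sigma = sig, dot = dots)
}

bf_metric_tensor <- function(traj) {
  vel <- bf_velocities(traj)
  g <- matrix(0, 2, 2); n <- 0
  for (r in seq_len(nrow(vel))) {
    if (vel$speed[r] == 0) next
    u <- c(vel$vx[r], vel$vy[r]) / vel$speed[r]
    g <- g + u %o% u; n <- n + 1
  }
  g / n
}

bf_order_param <- function(traj, L) {
  vel <- bf_velocities(traj)
  x0 <- min(vel$x); y0 <- min(vel$y)
  vals <- c()
  for (f in unique(vel$frame)) {
    sub <- vel[vel$frame == f, ]
    doms <- unique(cbind(floor((sub$x - x0) / L), floor((sub$y - y0) / L)))
    for (d in seq_len(nrow(doms))) {
      mem <- which(floor((sub$x - x0) / L) == doms[d, 1] &
                   floor((sub$y - y0) / L) == doms[d, 2])
      if (length(mem) < 2) next
      num <- sqrt(mean(sub$vx[mem])^2 + mean(sub$vy[mem])^2)
      den <- mean(sub$speed[mem])
      if (den > 0) vals <- c(vals, num / den)
    }
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

# half-ellipse perimeter by numeric quadrature (independent oracle)
half_ellipse_perimeter <- function(a, b) {
  f <- function(u) sqrt(b^2 * sin(u)^2 + a^2 * cos(u)^2)
  stats::integrate(f, 0, pi, rel.tol = 1e-10)$value
}
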