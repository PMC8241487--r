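# Free-ant trajectory characterization: finite-difference velocities, mean
# speed, anomalous mean-square displacement, polar order parameter scans,
# persistence length, pairwise directional correlation and the velocity
# metric tensor.

#' Finite-difference velocities
#'
#' Computes v = [x(t + gap*dt) - x(t)] / (gap*dt) across consecutive frames
#' of the same ant (gaps in tracking yield no velocity sample). Rows with
#' zero speed carry `NA` unit-direction components: a stationary ant has no
#' defined direction and contributes to no direction-based statistic.
#'
#' @param traj a [trajectory_table()].
#' @param frame_gap integer >= 1; velocities span `frame_gap` frames.
#' @return a `velocity_table` data.frame with columns `ant_id`, `frame`, `t`,
#'   `x`, `y` (start of the difference), `vx`, `vy`, `speed`, `ux`, `uy`,
#'   and attributes `mean_speed` (the ensemble mean speed v0), its standard
#'   error `mean_speed_se`, `frame_gap` and `dt` (the difference interval).
#' @export
compute_velocities <- function(traj, frame_gap = 1L) {
  stopifnot(inherits(traj, "trajectory_table"))
  if (frame_gap < 1L) stop("frame_gap must be >= 1")
  dt_frame <- attr(traj, "frame_interval")
  dt <- frame_gap * dt_frame
  parts <- split(seq_len(nrow(traj)), traj$ant_id)
  out <- lapply(parts, function(ix) {
    if (length(ix) < frame_gap + 1L) return(NULL)
    fr <- traj$frame[ix]
    j <- match(fr + frame_gap, fr)
    keep <- which(!is.na(j))
    if (!length(keep)) return(NULL)
    i0 <- ix[keep]; i1 <- ix[j[keep]]
    dtt <- traj$t[i1] - traj$t[i0]
    bad <- abs(dtt - dt) > 1e-6 * dt
    if (any(bad)) {
      stop("inconsistent frame interval for ant ", traj$ant_id[i0[1]],
           " at frame(s) ", paste(traj$frame[i0[bad]], collapse = ", "))
    }
    data.frame(ant_id = traj$ant_id[i0], frame = traj$frame[i0],
               t = traj$t[i0], x = traj$x[i0], y = traj$y[i0],
               vx = (traj$x[i1] - traj$x[i0]) / dtt,
               vy = (traj$y[i1] - traj$y[i0]) / dtt)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) stop("no ant has frame span >= frame_gap")
  rownames(out) <- NULL
  out$speed <- sqrt(out$vx^2 + out$vy^2)
  pos <- out$speed > 0
  out$ux <- ifelse(pos, out$vx / out$speed, NA_real_)
  out$uy <- ifelse(pos, out$vy / out$speed, NA_real_)
  structure(out,
            mean_speed = mean(out$speed), mean_speed_se = sem(out$speed),
            frame_gap = as.integer(frame_gap), dt = dt,
            n_zero_speed = sum(!pos),
            class = c("velocity_table", "data.frame"))
}

#' Mean-square displacement and anomalous-diffusion fit
#'
#' Ensemble MSD over all ants and (overlapping) start times,
#' \eqn{\langle x^2\rangle(\tau)}, followed by a least-squares fit of
#' \eqn{\log \langle x^2\rangle} vs \eqn{\log \tau} to the power law
#' \eqn{\langle x^2\rangle = 4 D \tau^\xi}. \eqn{\xi = 1} is ordinary
#' diffusion, \eqn{\xi = 2} ballistic motion.
#'
#' @param traj a [trajectory_table()].
#' @param max_lag largest lag, s.
#' @param min_duration only ants tracked at least this long (s) enter the
#'   ensemble (default 10 s).
#' @return an `msd_curve` data.frame (`tau`, `msd`, `n_obs`) with attributes
#'   `D` (l^2 s^-xi), `xi`, `fit` (the `lm`).
#' @export
msd_analysis <- function(traj, max_lag, min_duration = 10) {
  stopifnot(inherits(traj, "trajectory_table"))
  dt <- attr(traj, "frame_interval")
  kmax <- max(1L, floor(max_lag / dt))
  ss <- numeric(kmax); nn <- numeric(kmax)
  for (ix in split(seq_len(nrow(traj)), traj$ant_id)) {
    tt <- traj$t[ix]
    if (max(tt) - min(tt) < min_duration) next
    fr <- traj$frame[ix] - min(traj$frame[ix]) + 1L
    nf <- max(fr)
    xx <- rep(NA_real_, nf); yy <- rep(NA_real_, nf)
    xx[fr] <- traj$x[ix]; yy[fr] <- traj$y[ix]
    for (k in seq_len(min(kmax, nf - 1L))) {
      dx <- xx[-seq_len(k)] - xx[seq_len(nf - k)]
      dy <- yy[-seq_len(k)] - yy[seq_len(nf - k)]
      d2 <- dx^2 + dy^2
      ok <- is.finite(d2)
      ss[k] <- ss[k] + sum(d2[ok])
      nn[k] <- nn[k] + sum(ok)
    }
  }
  keep <- nn > 0
  curve <- data.frame(tau = (seq_len(kmax) * dt)[keep], msd = (ss / nn)[keep],
                      n_obs = nn[keep])
  if (all(curve$msd == 0)) {
    # stationary ensemble: MSD identically zero, no power law to fit
    return(structure(curve, D = 0, xi = NA_real_, fit = NULL,
                     class = c("msd_curve", "data.frame")))
  }
  if (sum(curve$msd > 0) < 3L) stop("fewer than 3 positive lags: cannot fit")
  fit <- stats::lm(log(msd) ~ log(tau), data = curve[curve$msd > 0, ])
  xi <- unname(stats::coef(fit)[2])
  D <- exp(unname(stats::coef(fit)[1])) / 4
  structure(curve, D = D, xi = xi, fit = fit,
            class = c("msd_curve", "data.frame"))
}

#' Polar order parameter in square domains
#'
#' For each domain size L the observation window (the bounding box of the
#' data) is tiled with L-by-L squares from its lower-left corner; in every
#' square holding at least two ants the normalized polar order
#' \eqn{|\varphi| = |\langle v\rangle| / \langle |v|\rangle} is computed and
#' then averaged over domains and frames. Single-occupant domains (where
#' \eqn{|\varphi| = 1} trivially) are excluded; an L with no multi-ant
#' domain reports `NA`, never zero.
#'
#' @param traj a [trajectory_table()].
#' @param L_values positive domain sizes, l.
#' @param frame_gap passed to [compute_velocities()].
#' @return an `order_scan` data.frame (`L`, `phi_abs`, `n_domains`).
#' @export
order_parameter_scan <- function(traj, L_values, frame_gap = 1L) {
  if (any(L_values <= 0)) stop("L_values must be positive")
  L_values <- sort(L_values)
  vel <- compute_velocities(traj, frame_gap)
  x0 <- min(vel$x); y0 <- min(vel$y)
  phi <- numeric(length(L_values)); ndom <- integer(length(L_values))
  for (li in seq_along(L_values)) {
    L <- L_values[li]
    cell <- paste(vel$frame, floor((vel$x - x0) / L),
                  floor((vel$y - y0) / L), sep = "/")
    nmem <- ave(vel$speed, cell, FUN = length)
    keep <- nmem >= 2
    if (!any(keep)) { phi[li] <- NA_real_; ndom[li] <- 0L; next }
    cc <- cell[keep]
    mvx <- tapply(vel$vx[keep], cc, mean)
    mvy <- tapply(vel$vy[keep], cc, mean)
    msp <- tapply(vel$speed[keep], cc, mean)
    vals <- sqrt(mvx^2 + mvy^2) / msp
    vals <- vals[is.finite(vals)]
    phi[li] <- mean(vals); ndom[li] <- length(vals)
  }
  structure(data.frame(L = L_values, phi_abs = phi, n_domains = ndom),
            class = c("order_scan", "data.frame"))
}

#' Persistence length from directional autocorrelation
#'
#' The directional autocorrelation \eqn{\langle \hat v_{i,0} \cdot
#' \hat v_{i,\tau}\rangle} is accumulated over all (ant, start-time)
#' observation pairs, binned by the distance travelled between the two
#' observations (`l_c`), and fitted by least squares to
#' \eqn{\exp(-l_c / l_p)} (log-linear). Two ensembles are offered: pooled
#' across ants, or per ant with the reported `l_p` the mean of the per-ant
#' fits (matching how a distribution over individuals is usually shown).
#'
#' @param traj a [trajectory_table()].
#' @param min_travel only ants whose cumulative travel reaches this distance
#'   (l) are used; default 5 l.
#' @param bin_width width of the `l_c` bins, l.
#' @param max_lc fit range cap, l; defaults to `3 * min_travel`.
#' @param mode `"per_ant"` (default) or `"pooled"`.
#' @param mask optional polygon (data.frame with `x`, `y`) delimiting the
#'   usable region: ants that ever come within `margin` of its boundary (or
#'   leave it) are excluded as edge-encountering.
#' @param margin exclusion margin around the mask boundary, l.
#' @return a `persistence_fit` list: `l_p`, `stderr`, `saturated` flag (TRUE
#'   when the correlation never decays, e.g. perfectly straight paths, and
#'   `l_p` is `Inf`), `curve` (pooled binned correlation), `per_ant`
#'   (data.frame of per-ant fits), `mode`, `n_ants`.
#' @export
persistence_length <- function(traj, min_travel = 5, bin_width = 0.5,
                               max_lc = NULL, mode = c("per_ant", "pooled"),
                               mask = NULL, margin = 2) {
  mode <- match.arg(mode)
  if (is.null(max_lc)) max_lc <- 3 * min_travel
  vel <- compute_velocities(traj, 1L)
  dt <- attr(vel, "dt")
  parts <- split(seq_len(nrow(vel)), vel$ant_id)

  if (!is.null(mask)) {
    keep_ant <- vapply(names(parts), function(a) {
      ix <- which(traj$ant_id == a)
      inside <- pracma::inpolygon(traj$x[ix], traj$y[ix], mask$x, mask$y)
      if (!all(inside)) return(FALSE)
      all(dist_to_polygon(traj$x[ix], traj$y[ix], mask$x, mask$y) > margin)
    }, logical(1))
    parts <- parts[keep_ant]
  }

  nbins <- ceiling(max_lc / bin_width)
  mids <- (seq_len(nbins) - 0.5) * bin_width
  pool_s <- numeric(nbins); pool_n <- numeric(nbins)
  per_ant <- list()

  fit_lp <- function(corr, n_obs) {
    use <- is.finite(corr) & corr > 0 & n_obs >= 5
    if (sum(use) < 3L) return(c(NA_real_, NA_real_))
    fit <- stats::lm(log(corr[use]) ~ mids[use], weights = n_obs[use])
    sl <- stats::coef(fit)[2]
    se <- summary(fit)$coefficients[2, 2]
    c(-1 / sl, se / sl^2)
  }

  for (a in names(parts)) {
    ix <- parts[[a]]
    # consecutive velocity samples only (no tracking gaps)
    fr <- vel$frame[ix]
    if (any(diff(fr) != 1L)) {
      runs <- split(ix, cumsum(c(0L, diff(fr) != 1L)))
    } else runs <- list(ix)
    a_s <- numeric(nbins); a_n <- numeric(nbins)
    travel_total <- 0
    for (run in runs) {
      ux <- vel$ux[run]; uy <- vel$uy[run]
      step <- vel$speed[run] * dt
      travel_total <- travel_total + sum(step)
      m <- length(run)
      if (m < 2L) next
      cum <- c(0, cumsum(step))
      for (k in seq_len(m - 1L)) {
        i0 <- seq_len(m - k)
        lc <- cum[i0 + k] - cum[i0]
        if (min(lc) > max_lc) break   # travel only grows with lag
        dots <- ux[i0] * ux[i0 + k] + uy[i0] * uy[i0 + k]
        ok <- is.finite(dots) & lc > 0 & lc <= max_lc
        if (!any(ok)) next
        b <- pmin(pmax(ceiling(lc[ok] / bin_width), 1L), nbins)
        sums <- rowsum(dots[ok], b)
        idx <- as.integer(rownames(sums))
        a_s[idx] <- a_s[idx] + sums[, 1]
        a_n <- a_n + tabulate(b, nbins)
      }
    }
    if (travel_total < min_travel) next
    pool_s <- pool_s + a_s; pool_n <- pool_n + a_n
    lp <- fit_lp(ifelse(a_n > 0, a_s / a_n, NA_real_), a_n)
    per_ant[[a]] <- data.frame(ant_id = a, l_p = lp[1], stderr = lp[2],
                               travel = travel_total)
  }
  if (!length(per_ant)) stop("no ant travelled at least min_travel")
  per_ant <- do.call(rbind, per_ant)
  rownames(per_ant) <- NULL
  corr <- ifelse(pool_n > 0, pool_s / pool_n, NA_real_)
  curve <- data.frame(l_c = mids, corr = corr, n_obs = pool_n)

  saturated <- all(corr[pool_n > 0] > exp(-1) - 1e-9) &&
    max(mids[pool_n > 0]) >= min_travel
  if (mode == "pooled") {
    lp <- fit_lp(corr, pool_n)
    l_p <- lp[1]; se <- lp[2]
  } else {
    vals <- per_ant$l_p[is.finite(per_ant$l_p) & per_ant$l_p > 0]
    l_p <- if (length(vals)) mean(vals) else NA_real_
    se <- sem(vals)
  }
  status <- "ok"
  if (saturated && (!is.finite(l_p) || l_p > 100 * max_lc || l_p < 0)) {
    l_p <- Inf; status <- "saturated"
  } else if (!is.finite(l_p) || l_p <= 0) {
    status <- "fit_failure"
  }
  structure(list(l_p = l_p, stderr = se, status = status,
                 saturated = saturated, curve = curve, per_ant = per_ant,
                 mode = mode, n_ants = nrow(per_ant)),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf("<persistence_fit> l_p = %.3g l (se %.2g), %s mode, %d ants, status: %s\n",
              x$l_p, x$stderr, x$mode, x$n_ants, x$status))
  invisible(x)
}

#' Pairwise directional correlation c(sigma, tau)
#'
#' \eqn{c(\sigma,\tau) = \langle \hat v_i(t) \cdot \hat v_j(t+\tau)\rangle}
#' over all ordered pairs of distinct ants, binned by the separation
#' \eqn{\sigma = |x_i(t) - x_j(t+\tau)|} (positions taken at the two
#' different times, as the statistic is defined; `same_time = TRUE` measures
#' separation at the common time t instead). A moving average over
#' `smooth_window` is applied along sigma. Bins with no pairs are `NA`.
#'
#' @param traj a [trajectory_table()].
#' @param tau_values time offsets, s (multiples of the frame interval).
#' @param bin_width sigma bin width, l.
#' @param smooth_window moving-average window along sigma, l (default 1 l).
#' @param max_sigma largest separation retained, l.
#' @param same_time logical; see above.
#' @return a `pair_correlation` data.frame (`sigma`, `tau`, `c`, `c_smooth`,
#'   `n_pairs`) with attribute `summary`: per tau, the pair-weighted mean c
#'   over all sigma and the implied mean separation angle (degrees).
#' @export
pair_correlation <- function(traj, tau_values = c(0, 1, 10), bin_width = 0.25,
                             smooth_window = 1, max_sigma = 20,
                             same_time = FALSE) {
  vel <- compute_velocities(traj, 1L)
  dt <- attr(traj, "frame_interval")
  frames <- sort(unique(vel$frame))
  by_frame <- split(seq_len(nrow(vel)), vel$frame)
  nbins <- ceiling(max_sigma / bin_width)
  mids <- (seq_len(nbins) - 0.5) * bin_width
  out <- list(); summ <- list()
  for (tau in tau_values) {
    k <- round(tau / dt)
    if (abs(k * dt - tau) > 1e-9) stop("tau must be a multiple of the frame interval")
    acc_s <- numeric(nbins); acc_n <- numeric(nbins)
    tot_s <- 0; tot_n <- 0
    for (f in frames) {
      i <- by_frame[[as.character(f)]]
      j <- by_frame[[as.character(f + k)]]
      if (is.null(j) || !length(i) || !length(j)) next
      ii <- i[is.finite(vel$ux[i])]
      jj <- j[is.finite(vel$ux[j])]
      if (!length(ii) || !length(jj)) next
      dots <- outer(vel$ux[ii], vel$ux[jj]) + outer(vel$uy[ii], vel$uy[jj])
      if (same_time) {
        # separation at the common time t needs ant j's position at frame f
        pj <- match(paste(vel$ant_id[jj], f), paste(vel$ant_id, vel$frame))
        ok_j <- !is.na(pj)
        jj <- jj[ok_j]; pj <- pj[ok_j]
        if (!length(jj)) next
        dots <- dots[, ok_j, drop = FALSE]
        sig <- sqrt(outer(vel$x[ii], vel$x[pj], `-`)^2 +
                    outer(vel$y[ii], vel$y[pj], `-`)^2)
      } else {
        sig <- sqrt(outer(vel$x[ii], vel$x[jj], `-`)^2 +
                    outer(vel$y[ii], vel$y[jj], `-`)^2)
      }
      same <- outer(vel$ant_id[ii], vel$ant_id[jj], `==`)
      use <- !same & sig <= max_sigma
      if (!any(use)) next
      b <- pmin(pmax(ceiling(sig[use] / bin_width), 1L), nbins)
      d <- dots[use]
      acc_n <- acc_n + tabulate(b, nbins)
      sums <- rowsum(d, b)
      acc_s[as.integer(rownames(sums))] <- acc_s[as.integer(rownames(sums))] + sums[, 1]
      tot_s <- tot_s + sum(d); tot_n <- tot_n + length(d)
    }
    cc <- ifelse(acc_n > 0, acc_s / acc_n, NA_real_)
    ok <- acc_n > 0
    cs <- rep(NA_real_, nbins)
    if (any(ok)) cs[ok] <- moving_average(cc[ok], mids[ok], smooth_window)
    out[[length(out) + 1L]] <-
      data.frame(sigma = mids, tau = tau, c = cc, c_smooth = cs, n_pairs = acc_n)
    mean_c <- if (tot_n > 0) tot_s / tot_n else NA_real_
    summ[[length(summ) + 1L]] <-
      data.frame(tau = tau, mean_c = mean_c, n_pairs = tot_n,
                 separation_angle_deg = separation_angle(mean_c))
  }
  structure(do.call(rbind, out), summary = do.call(rbind, summ),
            class = c("pair_correlation", "data.frame"))
}

#' Mean separation angle implied by a directional correlation
#'
#' The mean dot product of unit headings `c` maps to a nominal angular
#' separation `acos(c)`, reported in degrees.
#'
#' @param c correlation in \[-1, 1\].
#' @return angle in degrees.
#' @examples separation_angle(0.170)  # ~ 80 degrees
#' @export
separation_angle <- function(c) {
  ifelse(is.finite(c) & abs(c) <= 1, acos(c) * 180 / pi, NA_real_)
}

#' Velocity metric tensor
#'
#' \eqn{g^v = \langle \hat v \otimes \hat v \rangle_N} over all velocity
#' records with positive speed. Because unit vectors are used, the trace is
#' exactly 1 and isotropic traffic gives diag(0.5, 0.5). The principal
#' direction `g1` (largest eigenvalue) is oriented along the primary
#' direction of motion (sense of the net displacement); `g2` completes a
#' right-handed pair.
#'
#' @param vel a `velocity_table` from [compute_velocities()], or a 2-column
#'   matrix / data.frame of velocity vectors.
#' @return a `metric_tensor` list: `g` (2x2), `eigenvalues` (descending,
#'   summing to 1), `g1`, `g2`, `n`.
#' @export
velocity_metric_tensor <- function(vel) {
  if (inherits(vel, "velocity_table")) {
    ok <- is.finite(vel$ux)
    ux <- vel$ux[ok]; uy <- vel$uy[ok]
    mvx <- mean(vel$vx[ok]); mvy <- mean(vel$vy[ok])
  } else {
    vel <- as.matrix(vel)
    sp <- sqrt(vel[, 1]^2 + vel[, 2]^2)
    ok <- is.finite(sp) & sp > 0
    ux <- vel[ok, 1] / sp[ok]; uy <- vel[ok, 2] / sp[ok]
    mvx <- mean(vel[ok, 1]); mvy <- mean(vel[ok, 2])
  }
  if (length(ux) < 2L) stop("need at least 2 records with positive speed")
  g <- matrix(c(mean(ux^2), mean(ux * uy), mean(ux * uy), mean(uy^2)), 2L, 2L)
  eig <- eigen(g, symmetric = TRUE)
  g1 <- eig$vectors[, 1]
  if (sum(g1 * c(mvx, mvy)) < 0) g1 <- -g1
  g2 <- c(-g1[2], g1[1])   # right-handed
  structure(list(g = g, eigenvalues = eig$values, g1 = g1, g2 = g2,
                 n = length(ux)),
            class = "metric_tensor")
}

#' @export
print.metric_tensor <- function(x, ...) {
  cat(sprintf("<metric_tensor> diag = (%.3f, %.3f), off = %.3f, eigenvalues = (%.3f, %.3f), n = %d\n",
              x$g[1, 1], x$g[2, 2], x$g[1, 2],
              x$eigenvalues[1], x$eigenvalues[2], x$n))
  invisible(x)
}
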