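# Treadmilling rate estimators: packing fraction, contraction strain rate
# (areal and radial), structural exit rate, edge deposition rate and
# protrusion growth metrics. Internal units: body lengths (l) and seconds at
# the data level; rates are reported per minute, matching field convention.

#' Mean packing fraction of free ants
#'
#' \eqn{\bar\phi = (N_{tot} - A\rho_r) / (A\rho_r)}: free ants per
#' structural ant, given that the structural layer holds `A * rho_r` ants.
#'
#' @param n_total total number of ants.
#' @param A total raft area (l^2 or mm^2, consistent with `rho_r`).
#' @param rho_r structural ant density (ants per unit area).
#' @return dimensionless packing fraction (can exceed 1 when free ants
#'   outnumber structural ants).
#' @export
packing_fraction <- function(n_total, A, rho_r) {
  if (A <= 0 || rho_r <= 0) stop("A and rho_r must be positive")
  n_struct <- A * rho_r
  if (n_total < n_struct) {
    warning("n_total below the implied structural count: negative packing fraction")
  }
  (n_total - n_struct) / n_struct
}

new_rate_estimates <- function(...) {
  structure(list(...), class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat("<rate_estimates>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) == 1L) cat(sprintf("  %s: %.6g\n", nm, v))
  }
  invisible(x)
}

#' Contraction strain rate from areal decay
#'
#' Fits the circumscribed-area series to the isotropic-contraction law
#' \eqn{A_r = A_{r0} e^{-2\dot\varepsilon t}} (the factor 2 because areal
#' decay is the square of linear contraction). Default is a linear
#' least-squares fit of `log(A_r)` against time, exact on noiseless
#' exponential input; `method = "nls"` refits the exponential directly.
#'
#' @param series an [area_series()] (time in seconds).
#' @param method `"log_linear"` (default) or `"nls"`.
#' @return a `rate_estimates` list: `eps_dot` (1/min, > 0 = contraction),
#'   `eps_dot_se`, `A_r0`, `r_squared`, `growth` flag.
#' @export
fit_area_decay <- function(series, method = c("log_linear", "nls")) {
  method <- match.arg(method)
  if (nrow(series) < 3L) stop("need at least 3 time points")
  if (any(series$A_r <= 0)) stop("A_r must be positive throughout")
  t_min <- series$t / 60
  if (stats::sd(series$A_r) == 0) {
    return(new_rate_estimates(eps_dot = 0, eps_dot_se = 0,
                              A_r0 = series$A_r[1], r_squared = NA_real_,
                              growth = FALSE, method = "constant"))
  }
  fit <- stats::lm(log(A_r) ~ t_min, data = series)
  eps <- -unname(stats::coef(fit)[2]) / 2
  se <- suppressWarnings(summary(fit))$coefficients[2, 2] / 2
  A_r0 <- exp(unname(stats::coef(fit)[1]))
  if (method == "nls") {
    nfit <- stats::nls(A_r ~ A0 * exp(-2 * e * t_min), data = series,
                       start = list(A0 = A_r0, e = eps),
                       control = stats::nls.control(maxiter = 100,
                                                    scaleOffset = 1))
    eps <- unname(stats::coef(nfit)["e"])
    se <- summary(nfit)$coefficients["e", 2]
    A_r0 <- unname(stats::coef(nfit)["A0"])
  }
  pred <- A_r0 * exp(-2 * eps * t_min)
  r2 <- 1 - sum((series$A_r - pred)^2) / sum((series$A_r - mean(series$A_r))^2)
  if (eps < 0) warning("negative strain rate: the raft is growing")
  new_rate_estimates(eps_dot = eps, eps_dot_se = se, A_r0 = A_r0,
                     r_squared = r2, growth = eps < 0, method = method)
}

#' Radial velocity field toward an anchor
#'
#' Builds the (R, Rdot) field used by [fit_radial_strain()] from structural
#' trajectories: R is the distance from the anchor and Rdot the speed toward
#' it (\eqn{v \cdot \hat R} with \eqn{\hat R} pointing to the anchor),
#' converted to l/min.
#'
#' @param traj a [trajectory_table()] (typically `layer == "structural"`).
#' @param anchor length-2 numeric anchor position.
#' @param frame_gap finite-difference gap, frames.
#' @return a `radial_field` data.frame (`R` in l, `R_dot` in l/min).
#' @export
radial_field <- function(traj, anchor = c(0, 0), frame_gap = 1L) {
  vel <- compute_velocities(traj, frame_gap)
  rx <- anchor[1] - vel$x; ry <- anchor[2] - vel$y
  R <- sqrt(rx^2 + ry^2)
  ok <- R > 0
  R_dot <- (vel$vx[ok] * rx[ok] + vel$vy[ok] * ry[ok]) / R[ok] * 60
  structure(data.frame(R = R[ok], R_dot = R_dot),
            class = c("radial_field", "data.frame"))
}

#' Contraction strain rate from the radial velocity profile
#'
#' For isotropic contraction toward an anchor, \eqn{\dot R = \dot\varepsilon
#' R}; the strain rate is the slope of the linear least-squares fit of
#' `R_dot` on `R`. A non-zero intercept indicates a non-anchored flow
#' component and is reported as a diagnostic.
#'
#' @param field a `radial_field` (see [radial_field()]): columns `R` (l) and
#'   `R_dot` (l/min, positive toward the anchor).
#' @return a `rate_estimates` list: `eps_dot` (1/min), `eps_dot_se`,
#'   `intercept`, `r_squared`.
#' @export
fit_radial_strain <- function(field) {
  if (nrow(field) < 3L || length(unique(field$R)) < 3L) {
    stop("need at least 3 points with distinct R")
  }
  fit <- stats::lm(R_dot ~ R, data = field)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  new_rate_estimates(eps_dot = unname(co[2, 1]), eps_dot_se = unname(co[2, 2]),
                     intercept = unname(co[1, 1]), r_squared = sm$r.squared)
}

#' Structural exit rate from the contraction rate
#'
#' With conserved structural density, contraction forces structural ants out
#' of the network into the free layer at \eqn{\delta = 2\rho_r\dot\varepsilon}
#' per unit area (positive for contraction; the factor 2 because exit is an
#' areal phenomenon while \eqn{\dot\varepsilon} is linear), equivalently
#' \eqn{2\dot\varepsilon} per structural ant.
#'
#' @param eps_dot contraction strain rate, 1/min.
#' @param rho_r structural density, ants per unit area.
#' @return a `rate_estimates` list: `delta_area` (exits/min/area),
#'   `delta_per_ant` (exits/min per structural ant).
#' @export
exit_rate <- function(eps_dot, rho_r) {
  if (rho_r <= 0) stop("rho_r must be > 0")
  new_rate_estimates(delta_area = 2 * rho_r * eps_dot,
                     delta_per_ant = 2 * eps_dot)
}

#' Edge deposition rate from growth-area increments
#'
#' \eqn{\gamma = \dot A_g \rho_r / P} with \eqn{\dot A_g} the finite
#' difference of the newly deposited growth area and `P` the updated raft
#' perimeter; also reports \eqn{\alpha = \gamma P / A} in both per-unit-area
#' and per-structural-ant variants (the two conventions differ by the
#' factor `rho_r`).
#'
#' @param series an [area_series()].
#' @param rho_r structural density, ants/l^2.
#' @return a `rate_estimates` list: `gamma` (events/min/l), `gamma_se`,
#'   `alpha_area` (events/min per unit area times density, i.e.
#'   events/min/l^2), `alpha_per_ant` (1/min).
#' @export
edge_deposition_rate <- function(series, rho_r) {
  if (rho_r <= 0) stop("rho_r must be > 0")
  if (nrow(series) < 2L) stop("need at least 2 time points")
  if (any(series$P <= 0)) stop("perimeter must be positive")
  if (any(series$A_g / series$A > 0.2, na.rm = TRUE)) {
    warning("A_g exceeds 20% of A: update the tracked edge set more often")
  }
  dAg <- diff(series$A_g) / diff(series$t / 60)       # l^2 per min
  if (mean(dAg < 0) > 0.5) {
    warning("sustained negative growth-area increments: deposition model violated")
  }
  n <- nrow(series)
  Pmid <- (series$P[-1] + series$P[-n]) / 2
  Amid <- (series$A[-1] + series$A[-n]) / 2
  g_inst <- dAg * rho_r / Pmid
  gamma <- mean(g_inst)
  alpha_area <- mean(g_inst * Pmid / Amid)
  new_rate_estimates(gamma = gamma, gamma_se = sem(g_inst),
                     alpha_area = alpha_area,
                     alpha_per_ant = alpha_area / rho_r,
                     n_increments = n - 1L)
}

#' Protrusion growth rate and width
#'
#' Tracks a protrusion from a tip point series, two flank reference points
#' and an outline polygon per frame. `L` is the distance from the mean flank
#' position to the tip; `V` its finite-difference rate (l/min); `W` the mean
#' width `A_p / L_c` with `A_p` the outline area and `L_c` the centerline
#' length, taken as the extent of the outline projected on its principal
#' axis. Local contraction of the reference ants is not corrected for (it is
#' an order of magnitude smaller than tip growth in practice).
#'
#' @param tip_track data.frame `t, x, y` of the tip.
#' @param flank_refs list of two data.frames `t, x, y` on opposite flanks.
#' @param outline either one polygon (data.frame `x, y`) or a list of
#'   polygons, one per frame.
#' @return a `protrusion_track` data.frame (`t`, `L`, `V`, `A_p`, `L_c`,
#'   `W`) with attributes `mean_V`, `se_V`, `mean_W`, `se_W`.
#' @export
protrusion_metrics <- function(tip_track, flank_refs, outline) {
  stopifnot(length(flank_refs) == 2L)
  f1 <- flank_refs[[1]]; f2 <- flank_refs[[2]]
  if (any(sqrt((f1$x - f2$x)^2 + (f1$y - f2$y)^2) < 1e-9)) {
    stop("flank reference points coincide")
  }
  n <- nrow(tip_track)
  mx <- (f1$x + f2$x) / 2; my <- (f1$y + f2$y) / 2
  L <- sqrt((tip_track$x - mx)^2 + (tip_track$y - my)^2)
  V <- c(NA_real_, diff(L) / diff(tip_track$t / 60))
  if (is.data.frame(outline)) outline <- rep(list(outline), n)
  geom <- vapply(outline, function(poly) {
    A_p <- abs(polygon_area(poly$x, poly$y))
    ctr <- cbind(poly$x - mean(poly$x), poly$y - mean(poly$y))
    ax <- svd(ctr, nu = 0, nv = 1)$v[, 1]
    L_c <- diff(range(ctr %*% ax))
    c(A_p, L_c)
  }, numeric(2))
  A_p <- geom[1, ]; L_c <- geom[2, ]
  if (any(A_p <= 0) || any(L_c <= 0)) stop("degenerate protrusion outline")
  W <- A_p / L_c
  structure(data.frame(t = tip_track$t, L = L, V = V, A_p = A_p,
                       L_c = L_c, W = W),
            mean_V = mean(V, na.rm = TRUE), se_V = sem(V),
            mean_W = mean(W), se_W = sem(W),
            class = c("protrusion_track", "data.frame"))
}

#' Convert densities between per-mm^2 and per-body-length^2
#'
#' @param rho density, ants per mm^2.
#' @param ell_mm body length in mm (default 2.9).
#' @return density in ants per l^2.
#' @export
density_mm2_to_ell2 <- function(rho, ell_mm = 2.9) {
  if (ell_mm <= 0) stop("ell_mm must be > 0")
  rho * ell_mm^2
}
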