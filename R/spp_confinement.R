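# Overdamped self-propelled particles in convex confinement: interior
# ballistic motion with rotational diffusion, wall attachment on contact,
# gliding with the tangential projection of the propulsion, detachment when
# the heading points inward. In the strong-confinement limit the stationary
# wall density is curvature-weighted, rho_s(s) = kappa(s) / (2 pi).

polyline_closed_geometry <- function(x, y) {
  n <- length(x)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  seg <- sqrt((x[ip] - x)^2 + (y[ip] - y)^2)
  s <- c(0, cumsum(seg))[seq_len(n)]
  perim <- sum(seg)
  tx <- x[ip] - x[im]; ty <- y[ip] - y[im]
  tl <- sqrt(tx^2 + ty^2)
  tx <- tx / tl; ty <- ty / tl
  # CCW orientation assumed: outward normal is the tangent rotated -90 deg
  nx <- ty; ny <- -tx
  psi <- atan2(ny, nx)
  dpsi <- wrap_angle(psi[ip] - psi[im])
  ds <- (seg + seg[im])
  kappa <- dpsi / ds
  list(s = s, perimeter = perim, tx = tx, ty = ty, nx = nx, ny = ny,
       psi = psi, kappa = kappa)
}

#' Convex confinement domains
#'
#' A closed convex boundary represented as a dense counter-clockwise
#' polyline with precomputed arclength `s`, outward-normal orientation
#' `psi` and curvature `kappa` (circumscribed-angle finite differences).
#' Convexity (`kappa >= 0` everywhere, total turning 2 pi) is enforced.
#'
#' @param x,y boundary vertices, CCW, not repeating the first point.
#' @param type,params internal tags used for fast point-in-domain tests.
#' @return a `convex_domain` list.
#' @export
convex_domain <- function(x, y, type = "polygon", params = list()) {
  if (abs(polygon_area(x, y)) < 1e-12) stop("degenerate boundary")
  if (polygon_area(x, y) < 0) { x <- rev(x); y <- rev(y) }   # force CCW
  n <- length(x)
  ip <- c(2:n, 1L); ipp <- c(3:n, 1L, 2L)
  cross <- (x[ip] - x) * (y[ipp] - y[ip]) - (y[ip] - y) * (x[ipp] - x[ip])
  if (any(cross < -1e-9 * max(abs(cross)))) {
    stop("boundary is not convex (reflex vertex found)")
  }
  g <- polyline_closed_geometry(x, y)
  structure(c(list(x = x, y = y, type = type, params = params), g),
            class = "convex_domain")
}

#' @rdname convex_domain
#' @param radius circle radius, l.
#' @param n number of boundary vertices.
#' @export
domain_circle <- function(radius, n = 1024L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  convex_domain(radius * cos(th), radius * sin(th), type = "circle",
                params = list(radius = radius))
}

#' @rdname convex_domain
#' @param a,b ellipse semi-axes, l.
#' @export
domain_ellipse <- function(a, b, n = 1024L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  convex_domain(a * cos(th), b * sin(th), type = "ellipse",
                params = list(a = a, b = b))
}

#' @rdname convex_domain
#' @param vertices data.frame with `x`, `y` (convex polygon).
#' @export
domain_polygon <- function(vertices) {
  convex_domain(vertices$x, vertices$y, type = "polygon")
}

domain_inside <- function(domain, px, py) {
  switch(domain$type,
         circle = px^2 + py^2 <= domain$params$radius^2,
         ellipse = (px / domain$params$a)^2 + (py / domain$params$b)^2 <= 1,
         as.logical(pracma::inpolygon(px, py, domain$x, domain$y)))
}

# Arclength of the boundary point nearest to (px, py); vectorized over points.
domain_project_s <- function(domain, px, py) {
  vapply(seq_along(px), function(i) {
    d2 <- (domain$x - px[i])^2 + (domain$y - py[i])^2
    domain$s[which.min(d2)]
  }, numeric(1))
}

# Boundary position / frame fields at arclength s (linear interpolation).
domain_at_s <- function(domain, s) {
  P <- domain$perimeter
  s <- s %% P
  sv <- c(domain$s, P)
  i <- findInterval(s, sv, rightmost.closed = TRUE)
  i[i > length(domain$x)] <- length(domain$x)
  ip <- i %% length(domain$x) + 1L
  w <- (s - domain$s[i]) / (sv[i + 1L] - domain$s[i])
  list(x = (1 - w) * domain$x[i] + w * domain$x[ip],
       y = (1 - w) * domain$y[i] + w * domain$y[ip],
       tx = (1 - w) * domain$tx[i] + w * domain$tx[ip],
       ty = (1 - w) * domain$ty[i] + w * domain$ty[ip],
       nx = (1 - w) * domain$nx[i] + w * domain$nx[ip],
       ny = (1 - w) * domain$ny[i] + w * domain$ny[ip])
}

#' Curvature-weighted steady-state wall density
#'
#' The strong-confinement prediction for the stationary density of wall
#' residents per unit arclength, \eqn{\rho_s(s) = \kappa(s) / 2\pi}, which
#' integrates to exactly 1 around any closed convex boundary (total turning
#' is 2 pi).
#'
#' @param domain a [convex_domain()].
#' @return data.frame `s`, `rho_s` (1/l) with attribute `integral`.
#' @export
fily_steady_density <- function(domain) {
  stopifnot(inherits(domain, "convex_domain"))
  if (any(domain$kappa < -1e-9)) stop("negative curvature: not convex")
  rho <- domain$kappa / (2 * pi)
  n <- length(domain$s)
  ds <- diff(c(domain$s, domain$perimeter))
  integral <- sum(rho * ds)
  structure(data.frame(s = domain$s, rho_s = rho), integral = integral)
}

#' Simulate self-propelled particles in a convex domain
#'
#' Interior particles move at speed `v0` along a heading undergoing
#' rotational diffusion (correlation time `tau_r`); translation is
#' noiseless. A particle reaching the boundary attaches and glides with the
#' tangential projection of its propulsion,
#' \eqn{\dot s = v_0\,(\hat e(\theta) \cdot \hat t)}, and detaches as soon
#' as its heading points inward (\eqn{\hat e \cdot \hat n < 0}). With
#' `glide = "normal_angle"` the printed-convention alternative
#' \eqn{\dot s = v_0 \cos(\theta - \psi)} with `psi` the outward-normal
#' orientation is used instead (the two coincide when the angle is measured
#' from the tangent).
#'
#' @param domain a [convex_domain()].
#' @param p an [abp_params()] (`spread` is ignored; particles start uniform
#'   in the domain).
#' @param record_every record a state snapshot every this many seconds.
#' @param glide `"tangential"` (default) or `"normal_angle"`.
#' @param dt integration step, s; default
#'   `min(tau_r / 50, 0.1 * feature / v0)` with `feature` the minimum
#'   half-axis of the domain's bounding box.
#' @return an `spp_states` data.frame (`time`, `id`, `x`, `y`, `theta`,
#'   `on_wall`, `s`) with attributes `domain`, `dt`, `params`.
#' @export
simulate_confined_spp <- function(domain, p, record_every = 5,
                                  glide = c("tangential", "normal_angle"),
                                  dt = NULL) {
  stopifnot(inherits(domain, "convex_domain"), inherits(p, "abp_params"))
  glide <- match.arg(glide)
  feature <- min(diff(range(domain$x)), diff(range(domain$y))) / 2
  if (is.null(dt)) {
    dt <- min(p$tau_r / 50, if (p$v0 > 0) 0.1 * feature / p$v0 else Inf)
    dt <- min(dt, record_every)
  }
  l_p <- p$v0 * p$tau_r
  diam <- max(diff(range(domain$x)), diff(range(domain$y)))
  if (l_p <= diam) {
    message(sprintf(
      "note: persistence length %.3g l does not exceed the domain size %.3g l; confinement is not strong",
      l_p, diam))
  }
  set.seed(p$seed)
  n <- p$n_ants
  # uniform starting positions by rejection sampling in the bounding box
  px <- numeric(n); py <- numeric(n); filled <- 0L
  while (filled < n) {
    cx <- stats::runif(n, min(domain$x), max(domain$x))
    cy <- stats::runif(n, min(domain$y), max(domain$y))
    ok <- which(domain_inside(domain, cx, cy))
    take <- ok[seq_len(min(length(ok), n - filled))]
    px[filled + seq_along(take)] <- cx[take]
    py[filled + seq_along(take)] <- cy[take]
    filled <- filled + length(take)
  }
  theta <- stats::runif(n, -pi, pi)
  on_wall <- rep(FALSE, n)
  s_arc <- rep(NA_real_, n)
  n_steps <- ceiling(p$t_end / dt)
  rec_stride <- max(1L, round(record_every / dt))
  recs <- vector("list", n_steps %/% rec_stride + 1L)
  ri <- 0L
  for (k in seq_len(n_steps)) {
    theta <- wrap_angle(theta + stats::rnorm(n, sd = sqrt(2 * dt / p$tau_r)))
    ex <- cos(theta); ey <- sin(theta)
    # wall residents: detach if heading points inward, else glide
    if (any(on_wall)) {
      w <- which(on_wall)
      fr <- domain_at_s(domain, s_arc[w])
      edotn <- ex[w] * fr$nx + ey[w] * fr$ny
      det <- edotn < 0
      if (any(det)) {
        wd <- w[det]
        frd <- domain_at_s(domain, s_arc[wd])
        # re-enter the interior just inside the wall
        px[wd] <- frd$x - 1e-9 * frd$nx
        py[wd] <- frd$y - 1e-9 * frd$ny
        on_wall[wd] <- FALSE
        s_arc[wd] <- NA_real_
      }
      w <- which(on_wall)
      if (length(w)) {
        fr <- domain_at_s(domain, s_arc[w])
        sd_ <- if (glide == "tangential") {
          p$v0 * (ex[w] * fr$tx + ey[w] * fr$ty)
        } else {
          p$v0 * cos(theta[w] - atan2(fr$ny, fr$nx))
        }
        s_arc[w] <- (s_arc[w] + sd_ * dt) %% domain$perimeter
        fr <- domain_at_s(domain, s_arc[w])
        px[w] <- fr$x; py[w] <- fr$y
      }
    }
    # interior particles advance ballistically; attach on boundary contact
    int_ <- which(!on_wall)
    if (length(int_)) {
      nx_ <- px[int_] + p$v0 * ex[int_] * dt
      ny_ <- py[int_] + p$v0 * ey[int_] * dt
      inside <- domain_inside(domain, nx_, ny_)
      stay <- int_[inside]
      px[stay] <- nx_[inside]; py[stay] <- ny_[inside]
      hit <- int_[!inside]
      if (length(hit)) {
        s_new <- domain_project_s(domain, nx_[!inside], ny_[!inside])
        fr <- domain_at_s(domain, s_new)
        px[hit] <- fr$x; py[hit] <- fr$y
        s_arc[hit] <- s_new
        on_wall[hit] <- TRUE
      }
    }
    if (k %% rec_stride == 0L) {
      ri <- ri + 1L
      recs[[ri]] <- data.frame(time = k * dt, id = seq_len(n), x = px, y = py,
                               theta = theta, on_wall = on_wall, s = s_arc)
    }
  }
  out <- do.call(rbind, recs[seq_len(ri)])
  structure(out, domain = domain, dt = dt, params = p,
            class = c("spp_states", "data.frame"))
}

#' Wall residence density along the boundary
#'
#' Normalized histogram of wall-resident particles per unit arclength over
#' the steady-state window, with the curvature-weighted reference
#' \eqn{\kappa / 2\pi} attached per bin for comparison.
#'
#' @param states an `spp_states` from [simulate_confined_spp()].
#' @param domain the [convex_domain()] used (defaults to the one attached to
#'   `states`).
#' @param bins number of equal arclength bins.
#' @param burn_in discard records before this time, s.
#' @return data.frame (`s_mid`, `density`, `kappa_ref`, `n`) with attribute
#'   `wall_fraction` (share of retained records that are wall-resident);
#'   the density integrates to 1.
#' @export
boundary_residence_density <- function(states, domain = NULL, bins = 36L,
                                       burn_in = 0) {
  if (is.null(domain)) domain <- attr(states, "domain")
  keep <- states$time >= burn_in
  wall <- keep & states$on_wall
  if (!any(wall)) stop("no wall-resident records after burn-in")
  P <- domain$perimeter
  bw <- P / bins
  b <- pmin(floor(states$s[wall] / bw) + 1L, bins)
  counts <- tabulate(b, bins)
  density <- counts / (sum(counts) * bw)
  s_mid <- (seq_len(bins) - 0.5) * bw
  ref <- fily_steady_density(domain)
  kappa_ref <- stats::approx(c(ref$s, P), c(ref$rho_s, ref$rho_s[1]),
                             xout = s_mid, rule = 2)$y
  structure(data.frame(s_mid = s_mid, density = density,
                       kappa_ref = kappa_ref, n = counts),
            wall_fraction = sum(wall) / sum(keep),
            class = c("residence_density", "data.frame"))
}
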