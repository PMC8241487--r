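# Internal geometry and smoothing helpers shared across modules.

# Wrap angles to (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

# Arclength-weighted moving average of x sampled at (sorted) positions s.
# Each output value is the mean of all samples within +/- window/2.
moving_average <- function(x, s, window) {
  if (window <= 0 || length(x) < 2L) return(x)
  eps <- 1e-12
  cs <- c(0, cumsum(x))
  lo <- findInterval(s - window / 2 - eps, s) + 1L
  hi <- findInterval(s + window / 2 + eps, s)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Shoelace signed area of a polygon given by vertex vectors (not closed).
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Perimeter of a polygon / polyline.
polyline_length <- function(x, y, closed = FALSE) {
  dx <- diff(x); dy <- diff(y)
  len <- sum(sqrt(dx^2 + dy^2))
  if (closed) len <- len + sqrt((x[1] - x[length(x)])^2 + (y[1] - y[length(y)])^2)
  len
}

# Minimum distance from points (px, py) to the polygon boundary (closed).
dist_to_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- c(2:n, 1L)
  ax <- vx; ay <- vy; bx <- vx[j]; by <- vy[j]
  ex <- bx - ax; ey <- by - ay
  el2 <- ex^2 + ey^2
  out <- numeric(length(px))
  for (i in seq_along(px)) {
    tt <- ((px[i] - ax) * ex + (py[i] - ay) * ey) / el2
    tt <- pmin(pmax(tt, 0), 1)
    qx <- ax + tt * ex; qy <- ay + tt * ey
    out[i] <- sqrt(min((px[i] - qx)^2 + (py[i] - qy)^2))
  }
  out
}

# TRUE where any pair of non-adjacent segments of a polyline intersects.
polyline_self_intersects <- function(x, y, closed = FALSE) {
  n <- length(x)
  if (closed) { x <- c(x, x[1]); y <- c(y, y[1]) }
  m <- length(x) - 1L           # segments
  if (m < 3L) return(FALSE)
  ax <- x[-length(x)]; ay <- y[-length(y)]
  bx <- x[-1L]; by <- y[-1L]
  cross2 <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(m - 2L)) {
    j <- seq.int(i + 2L, m)
    if (closed && i == 1L) j <- j[j != m]   # first and last segment are adjacent
    if (!length(j)) next
    d1 <- cross2(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
    d2 <- cross2(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
    d3 <- cross2(ax[j], ay[j], bx[j], by[j], ax[i], ay[i])
    d4 <- cross2(ax[j], ay[j], bx[j], by[j], bx[i], by[i])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# Standard error of the mean, NA-safe.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
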