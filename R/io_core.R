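#' Build and validate a trajectory table
#'
#' The universal analysis input: time-stamped planar positions of identified
#' individuals. Positions are expressed in ant body lengths (l) and time in
#' seconds. Each row is one (ant, frame) observation; frames may have gaps
#' (these are allowed and flagged in the `gaps` attribute).
#'
#' @param df data.frame with columns `ant_id`, `frame`, `t`, `x`, `y` and
#'   optionally `layer` (`"free"` or `"structural"`; defaults to `"free"`).
#' @param frame_interval frame interval in seconds; inferred from the data
#'   when `NULL`.
#' @return a `trajectory_table`: the validated data.frame, ordered by
#'   (ant_id, frame), with attributes `frame_interval` and `gaps`.
#' @examples
#' tr <- trajectory_table(data.frame(
#'   ant_id = "a1", frame = 0:3, t = 0:3, x = c(0, 1, 2, 3), y = 0))
#' @export
trajectory_table <- function(df, frame_interval = NULL) {
  required <- c("ant_id", "frame", "t", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("trajectory table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$layer)) df$layer <- "free"
  if (!all(df$layer %in% c("free", "structural"))) {
    stop("layer must be 'free' or 'structural'")
  }
  df <- df[order(df$ant_id, df$frame), c(required, "layer"), drop = FALSE]
  df$ant_id <- as.character(df$ant_id)
  rownames(df) <- NULL
  if (anyDuplicated(df[, c("ant_id", "frame")])) {
    d <- df[duplicated(df[, c("ant_id", "frame")]), ]
    stop("duplicated (ant_id, frame) pair(s), e.g. ant ", d$ant_id[1],
         " frame ", d$frame[1])
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$t))) {
    stop("non-finite coordinate or time values")
  }
  bad <- tapply(df$t, df$ant_id, function(tt) any(diff(tt) <= 0))
  if (any(unlist(bad))) {
    stop("non-monotone time within ant(s): ",
         paste(names(bad)[unlist(bad)], collapse = ", "))
  }
  dts <- unlist(tapply(df$t, df$ant_id, diff, simplify = FALSE))
  dfr <- unlist(tapply(df$frame, df$ant_id, diff, simplify = FALSE))
  per_frame <- dts / dfr
  if (is.null(frame_interval)) {
    frame_interval <- if (length(per_frame)) stats::median(per_frame) else 1
  }
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  gaps <- sum(dfr > 1L)
  if (length(per_frame) &&
      any(abs(per_frame - frame_interval) > 1e-6 * frame_interval)) {
    stop("frame interval inconsistent with time stamps for some ants")
  }
  structure(df,
            frame_interval = frame_interval,
            gaps = gaps,
            class = c("trajectory_table", "data.frame"))
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat(sprintf("<trajectory_table> %d ants, %d records, dt = %g s, %d gap(s)\n",
              length(unique(x$ant_id)), nrow(x),
              attr(x, "frame_interval"), attr(x, "gaps")))
  NextMethod()
}

#' Read / write trajectory tables
#'
#' Delimited text, one row per (ant, frame), columns
#' `ant_id,frame,t_s,x_l,y_l,layer` (units: seconds and body lengths).
#' Coordinates are written with 8 significant digits so a write/read
#' round-trip preserves them to well within 6 significant digits.
#'
#' @param path file path.
#' @param dialect list of format options: `sep` (default `","`), and optional
#'   column-name overrides `id_col`, `frame_col`, `t_col`, `x_col`, `y_col`,
#'   `layer_col`.
#' @return `read_trajectories` returns a [trajectory_table()];
#'   `write_trajectories` returns `path` invisibly.
#' @export
read_trajectories <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- dialect$sep %||% ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  cols <- list(ant_id = dialect$id_col %||% "ant_id",
               frame  = dialect$frame_col %||% "frame",
               t      = dialect$t_col %||% "t_s",
               x      = dialect$x_col %||% "x_l",
               y      = dialect$y_col %||% "y_l")
  missing_cols <- setdiff(unlist(cols), names(raw))
  if (length(missing_cols)) {
    stop("trajectory file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(ant_id = raw[[cols$ant_id]], frame = raw[[cols$frame]],
                   t = raw[[cols$t]], x = raw[[cols$x]], y = raw[[cols$y]])
  layer_col <- dialect$layer_col %||% "layer"
  if (layer_col %in% names(raw)) df$layer <- raw[[layer_col]]
  trajectory_table(df)
}

#' @rdname read_trajectories
#' @param traj a [trajectory_table()].
#' @export
write_trajectories <- function(traj, path) {
  out <- data.frame(ant_id = traj$ant_id, frame = traj$frame,
                    t_s = signif(traj$t, 8), x_l = signif(traj$x, 8),
                    y_l = signif(traj$y, 8), layer = traj$layer)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build and validate an area series
#'
#' Time series of raft areas: `A_r` is the area circumscribed by a tracked
#' set of edge ants, `A` the total raft area, `A_g = A - A_r` the newly
#' deposited growth area and `P` the raft perimeter. Units l^2 and l.
#'
#' @param t time, seconds.
#' @param A_r,A,P area (l^2) and perimeter (l) series.
#' @param A_g optional growth-area series; computed as `A - A_r` if `NULL`,
#'   checked for consistency (1% relative tolerance) otherwise.
#' @return an `area_series` data.frame with columns `t, A_r, A, A_g, P`.
#' @export
area_series <- function(t, A_r, A, P, A_g = NULL) {
  if (any(A_r < 0) || any(A < A_r - 1e-9 * pmax(A, 1))) {
    stop("need A >= A_r >= 0")
  }
  if (any(P <= 0)) stop("perimeter must be positive")
  if (is.null(A_g)) A_g <- A - A_r
  if (any(abs(A_g - (A - A_r)) > 0.01 * pmax(A, 1))) {
    stop("A_g inconsistent with A - A_r")
  }
  structure(data.frame(t = t, A_r = A_r, A = A, A_g = A_g, P = P),
            class = c("area_series", "data.frame"))
}

#' Read / write area series
#'
#' CSV with columns `t_s,Ar_l2,A_l2,Ag_l2,P_l`.
#' @param path file path.
#' @return `read_area_series` returns an [area_series()].
#' @export
read_area_series <- function(path) {
  raw <- utils::read.csv(path, comment.char = "#")
  need <- c("t_s", "Ar_l2", "A_l2", "Ag_l2", "P_l")
  if (length(setdiff(need, names(raw)))) {
    stop("area-series file lacks column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  area_series(raw$t_s, raw$Ar_l2, raw$A_l2, raw$P_l, A_g = raw$Ag_l2)
}

#' @rdname read_area_series
#' @param series an [area_series()].
#' @export
write_area_series <- function(series, path) {
  out <- data.frame(t_s = series$t, Ar_l2 = signif(series$A_r, 8),
                    A_l2 = signif(series$A, 8), Ag_l2 = signif(series$A_g, 8),
                    P_l = signif(series$P, 8))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write boundary meshes
#'
#' Ordered vertex CSV (`vertex_index,x_l,y_l`) with an open/closed flag kept
#' in a header comment line, so a mesh round-trips through plain text.
#'
#' @param path file path.
#' @param mesh a `boundary_mesh` (see [init_half_ellipse()]) or any list with
#'   fields `x`, `y`, `closed`.
#' @return `read_mesh` returns a `boundary_mesh` with recomputed geometry.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# closed: %s", isTRUE(mesh$closed)), con)
  utils::write.csv(data.frame(vertex_index = seq_along(mesh$x) - 1L,
                              x_l = signif(mesh$x, 8), y_l = signif(mesh$y, 8)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  first <- readLines(path, n = 1L)
  closed <- grepl("closed:\\s*TRUE", first)
  raw <- utils::read.csv(path, comment.char = "#")
  boundary_mesh(raw$x_l, raw$y_l, closed = closed)
}

#' Write stage results to structured text
#'
#' Serializes any stage output (rate estimates, metric tensors, curves,
#' growth metrics) to JSON with stable key names. Data frames become column
#' tables; S3 objects are unclassed to named lists.
#'
#' @param results a list or S3 object of results.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  strip <- function(x) {
    if (is.data.frame(x)) return(as.list(x))
    if (inherits(x, "lm")) return(NULL)
    if (is.list(x)) {
      x <- unclass(x)
      attrs <- attributes(x)
      keep <- attrs[setdiff(names(attrs), c("names", "row.names", "class"))]
      out <- lapply(x, strip)
      out <- out[!vapply(out, is.null, logical(1))]
      if (length(keep)) out <- c(out, lapply(keep, strip))
      return(out)
    }
    x
  }
  jsonlite::write_json(strip(results), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run configuration
#'
#' Flat named parameter groups for every stage plus a random seed. Unknown
#' keys are rejected so typos in configuration files surface immediately.
#'
#' @param simulation,fitting,growth named lists of stage parameters.
#' @param seed integer random seed.
#' @param units list of unit conventions; `ell_mm` is the body length in mm
#'   used to convert between per-l^2 and per-mm^2 densities (default 2.9).
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = list(), fitting = list(), growth = list(),
                       seed = 1L, units = list(ell_mm = 2.9)) {
  known <- list(
    simulation = c("v0", "tau_r", "n_ants", "t_end", "dt", "eps_dot", "rho_r",
                   "gamma", "n_structural0", "anchor", "width", "length",
                   "bias_speed", "spread", "domain", "radius", "a", "b",
                   "burn_in", "bins"),
    fitting = c("frame_gap", "max_lag", "min_travel", "bin_width",
                "smooth_window", "L_values", "tau_values", "min_duration",
                "mode", "margin"),
    growth = c("a", "gamma0", "rho0", "beta", "phi_hat", "rho_r", "dt",
               "t_end", "spacing", "smooth_window", "minor_axis", "major_axis",
               "n_vertices", "full_axes", "snapshots"))
  for (grp in names(known)) {
    vals <- get(grp)
    unknown <- setdiff(names(vals), known[[grp]])
    if (length(unknown)) {
      stop("unknown ", grp, " config key(s): ", paste(unknown, collapse = ", "))
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  if (!is.null(units$ell_mm) && units$ell_mm <= 0) stop("ell_mm must be > 0")
  structure(list(simulation = simulation, fitting = fitting, growth = growth,
                 seed = as.integer(seed), units = units),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
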