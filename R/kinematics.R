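# Trajectory standardization and per-trial kinematic metrics.
#
# Raw pixel paths are remapped into the tracker's standard coordinate space
# (start button at the origin, response-box centres at (-1, 1.5) and
# (1, 1.5)), mirrored so every standardized path moves leftward, and
# time-normalized to 101 frames by linear interpolation.

N_FRAMES <- 101L

#' Default screen geometry for the double-choice task
#'
#' Pixel layout of the task screen: the START button sits bottom-centre and
#' the two response boxes sit in the upper corners. The remapping in
#' [remap_trajectory()] sends the start point to (0, 0) and the box centres
#' to (-1, 1.5) / (1, 1.5).
#'
#' @return A list with `screen` (width/height), `start` (x/y), box centres
#'   `box_left`, `box_right`, and `box_size` (w/h), all in pixels.
#' @export
default_geometry <- function() {
  list(
    screen = c(width = 1920, height = 1080),
    start = c(x = 960, y = 994),
    box_left = c(x = 240, y = 130),
    box_right = c(x = 1680, y = 130),
    box_size = c(w = 340, h = 220)
  )
}

validate_geometry <- function(geometry) {
  need <- c("screen", "start", "box_left", "box_right", "box_size")
  if (!all(need %in% names(geometry))) {
    abort("geometry must have screen, start, box_left, box_right, box_size")
  }
  if (geometry$box_left["x"] >= geometry$box_right["x"]) {
    abort("left response box must lie left of the right response box")
  }
  half_h <- geometry$box_size[["h"]] / 2
  if (geometry$start[["y"]] <= geometry$box_left[["y"]] + half_h) {
    abort("start point must lie below the response boxes")
  }
  invisible(geometry)
}

# pixel -> normalized affine map (and its inverse, used by the generator)
norm_scale <- function(geometry) {
  sx <- (geometry$box_right[["x"]] - geometry$box_left[["x"]]) / 2
  sy <- (geometry$start[["y"]] - geometry$box_left[["y"]]) / 1.5
  c(sx = sx, sy = sy)
}

px_to_norm <- function(x_px, y_px, geometry) {
  s <- norm_scale(geometry)
  cx <- (geometry$box_left[["x"]] + geometry$box_right[["x"]]) / 2
  list(
    x = (x_px - cx) / s[["sx"]],
    y = (geometry$start[["y"]] - y_px) / s[["sy"]]
  )
}

norm_to_px <- function(x, y, geometry) {
  s <- norm_scale(geometry)
  cx <- (geometry$box_left[["x"]] + geometry$box_right[["x"]]) / 2
  list(
    x_px = cx + x * s[["sx"]],
    y_px = geometry$start[["y"]] - y * s[["sy"]]
  )
}

#' Remap a raw pixel trajectory into the standard coordinate space
#'
#' Maps the start point to (0, 0) and the response-box centres to (-1, 1.5)
#' and (1, 1.5), with y increasing toward the boxes. Trials whose click
#' landed in the right box are mirrored about x = 0 so that every
#' standardized path moves leftward; the `mirrored` attribute records this.
#' Samples outside the screen are clamped with a warning.
#'
#' @param raw A data frame with columns `t_ms`, `x_px`, `y_px` (one trial).
#' @param geometry Screen geometry, see [default_geometry()].
#' @return A tibble `t_ms`, `x`, `y` in normalized space with attributes
#'   `mirrored` (logical) and `response_side` (`"left"`/`"right"`).
#' @export
remap_trajectory <- function(raw, geometry = default_geometry()) {
  validate_geometry(geometry)
  if (!all(c("t_ms", "x_px", "y_px") %in% names(raw))) {
    abort("`raw` must have columns t_ms, x_px, y_px")
  }
  x_px <- raw$x_px
  y_px <- raw$y_px
  w <- geometry$screen[["width"]]
  h <- geometry$screen[["height"]]
  if (any(x_px < 0 | x_px > w | y_px < 0 | y_px > h)) {
    warn("trajectory samples outside screen bounds; clamping")
    x_px <- pmin(pmax(x_px, 0), w)
    y_px <- pmin(pmax(y_px, 0), h)
  }
  p <- px_to_norm(x_px, y_px, geometry)
  side <- if (p$x[length(p$x)] > 0) "right" else "left"
  mirrored <- side == "right"
  x <- if (mirrored) -p$x else p$x
  out <- tibble(t_ms = raw$t_ms, x = x, y = p$y)
  attr(out, "mirrored") <- mirrored
  attr(out, "response_side") <- side
  out
}

#' Movement initiation time
#'
#' Time of the first sample whose displacement from the start position
#' exceeds the movement-onset threshold `epsilon` (default 0: the first
#' coordinate change). If the pointer never moves, the total duration is
#' returned with attribute `no_movement = TRUE`.
#'
#' @param path A data frame with `t_ms` and either `x`/`y` or `x_px`/`y_px`.
#' @param epsilon Movement-onset displacement threshold, in the path's
#'   coordinate units.
#' @return Initiation time in ms.
#' @export
initiation_time <- function(path, epsilon = 0) {
  xy <- path_xy(path)
  if (nrow(xy) < 1) abort("empty trajectory")
  d <- sqrt((xy$x - xy$x[1])^2 + (xy$y - xy$y[1])^2)
  idx <- which(d > epsilon)
  if (length(idx) == 0) {
    out <- path$t_ms[nrow(xy)] - path$t_ms[1]
    attr(out, "no_movement") <- TRUE
    return(out)
  }
  path$t_ms[idx[1]] - path$t_ms[1]
}

path_xy <- function(path) {
  if (all(c("x", "y") %in% names(path))) {
    tibble(x = path$x, y = path$y)
  } else if (all(c("x_px", "y_px") %in% names(path))) {
    tibble(x = path$x_px, y = path$y_px)
  } else {
    abort("path must have x/y or x_px/y_px columns")
  }
}

#' Time-normalize a trajectory to 101 frames
#'
#' Resamples the movement phase of a trajectory onto 101 equally spaced time
#' frames spanning movement onset to the click, by linear interpolation of
#' each coordinate. Movement onset is the last sample still at the start
#' position, so frame 0 sits at the origin of the movement. A path already
#' sampled on the 101-frame grid is returned unchanged (up to float
#' round-off).
#'
#' @param path A normalized-space trajectory from [remap_trajectory()] (or
#'   any `t_ms`/`x`/`y` frame with strictly increasing time).
#' @return A `standard_trajectory`: a 101-row tibble `frame`, `x`, `y` with
#'   attributes `onset_ms`, `it_ms`, `rt_ms` and `mirrored`.
#' @export
time_normalize <- function(path) {
  if (nrow(path) < 2) abort("need at least 2 samples to time-normalize")
  if (any(diff(path$t_ms) <= 0)) abort("timestamps must be strictly increasing")
  xy <- path_xy(path)
  d <- sqrt((xy$x - xy$x[1])^2 + (xy$y - xy$y[1])^2)
  moved <- which(d > 0)
  onset_idx <- if (length(moved) == 0) 1L else max(1L, moved[1] - 1L)
  t0 <- path$t_ms[onset_idx]
  t1 <- path$t_ms[nrow(path)]
  grid <- seq(t0, t1, length.out = N_FRAMES)
  keep <- seq(onset_idx, nrow(path))
  fx <- approx(path$t_ms[keep], xy$x[keep], xout = grid, ties = "ordered")$y
  fy <- approx(path$t_ms[keep], xy$y[keep], xout = grid, ties = "ordered")$y
  out <- tibble(frame = 0:(N_FRAMES - 1L), x = fx, y = fy)
  class(out) <- c("standard_trajectory", class(out))
  attr(out, "onset_ms") <- t0
  attr(out, "it_ms") <- initiation_time(path)
  attr(out, "rt_ms") <- t1 - path$t_ms[1]
  attr(out, "mirrored") <- isTRUE(attr(path, "mirrored"))
  attr(out, "response_side") <- attr(path, "response_side")
  out
}

#' Standardize one raw trial
#'
#' Convenience wrapper: [remap_trajectory()] then [time_normalize()].
#'
#' @inheritParams remap_trajectory
#' @return A `standard_trajectory` (see [time_normalize()]).
#' @export
standardize_trial <- function(raw, geometry = default_geometry()) {
  time_normalize(remap_trajectory(raw, geometry))
}

# signed perpendicular distances of every frame from the start->end chord;
# positive toward the non-chosen response side
signed_deviations <- function(st) {
  x <- st$x
  y <- st$y
  vx <- x[N_FRAMES] - x[1]
  vy <- y[N_FRAMES] - y[1]
  len <- sqrt(vx^2 + vy^2)
  if (len < 1e-12) abort("degenerate trajectory: start and end coincide")
  cross <- (vx * (y - y[1]) - vy * (x - x[1])) / len
  # non-chosen box: endpoint reflected about the start's vertical axis
  ref <- vx * (y[N_FRAMES] - y[1]) - vy * (-x[N_FRAMES] + 2 * x[1] - x[1])
  sgn <- if (ref >= 0) 1 else -1
  cross * sgn
}

#' Maximum deviation and its latency
#'
#' The maximum deviation (MD) is the largest perpendicular distance between
#' the trajectory and the ideal straight line joining its first and last
#' frame, signed positive toward the non-chosen response side. Its latency
#' (`md_time_ms`) is reported on the trial clock (question onset), so it
#' includes the initiation time.
#'
#' @param st A `standard_trajectory` from [time_normalize()].
#' @return A one-row tibble `md`, `md_time_ms`, `md_frame`.
#' @export
max_deviation <- function(st) {
  dev <- signed_deviations(st)
  idx <- which.max(abs(dev))
  onset <- attr(st, "onset_ms") %||% 0
  rt <- attr(st, "rt_ms") %||% onset
  md_time <- onset + (idx - 1) / (N_FRAMES - 1) * (rt - onset)
  tibble(md = dev[idx], md_time_ms = md_time, md_frame = idx - 1L)
}

#' Geometric area between trajectory and ideal line
#'
#' Signed shoelace area of the closed polygon formed by the trajectory plus
#' the reversed ideal segment, positive toward the non-chosen response side.
#' Paths that backtrack along the line direction can accumulate area beyond
#' `|MD| * line length` (regions swept twice count twice).
#'
#' @inheritParams max_deviation
#' @return Signed area (normalized space units squared).
#' @export
area_under_curve <- function(st) {
  x <- st$x
  y <- st$y
  vx <- x[N_FRAMES] - x[1]
  if (abs(vx) < 1e-12 && abs(y[N_FRAMES] - y[1]) < 1e-12) {
    abort("degenerate trajectory: start and end coincide")
  }
  # closed polygon: path vertices then straight back to the start
  shoelace <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  # orientation so that deviation toward the non-chosen side is positive:
  # a leftward path (end left of start) keeps the raw shoelace sign
  sgn <- if (x[N_FRAMES] <= x[1]) 1 else -1
  shoelace * sgn
}

#' Count direction flips along one axis
#'
#' Number of sign reversals of successive non-zero per-frame increments
#' along `axis`. Zero increments are skipped.
#'
#' @inheritParams max_deviation
#' @param axis `"x"` or `"y"`.
#' @param tol Increments with absolute value below `tol` count as zero.
#' @return Integer flip count.
#' @export
count_flips <- function(st, axis = c("x", "y"), tol = 1e-9) {
  axis <- match.arg(axis)
  inc <- diff(st[[axis]])
  s <- sign(inc[abs(inc) > tol])
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Mean per-frame velocity and acceleration
#'
#' Per-frame increments `v = X_n - X_(n-1)` (100 values per axis) and
#' `a = v_n - v_(n-1)` (99 values per axis), summarised by their signed
#' means. By default the x axis is un-mirrored first (restored to the real
#' response direction), so that the yes/no response mix of a participant is
#' reflected in the sign of the mean horizontal velocity.
#'
#' @inheritParams max_deviation
#' @param unmirror Restore the true left/right direction on mirrored trials
#'   before differencing (default `TRUE`).
#' @param absolute Report means of absolute increments instead of signed
#'   means.
#' @return A one-row tibble `v_x`, `v_y`, `a_x`, `a_y`.
#' @export
frame_kinematics <- function(st, unmirror = TRUE, absolute = FALSE) {
  xs <- st$x
  if (unmirror && isTRUE(attr(st, "mirrored"))) xs <- -xs
  vx <- diff(xs)
  vy <- diff(st$y)
  ax <- diff(vx)
  ay <- diff(vy)
  f <- if (absolute) function(z) mean(abs(z)) else mean
  tibble(v_x = f(vx), v_y = f(vy), a_x = f(ax), a_y = f(ay))
}

#' All per-trial metrics for one raw trajectory
#'
#' Standardizes the trial and computes the seven spatio-temporal metrics
#' (initiation time, reaction time, maximum-deviation latency, maximum
#' deviation, area under the curve, x- and y-flips) plus the four mean
#' velocity/acceleration components.
#'
#' @inheritParams remap_trajectory
#' @return A one-row tibble with columns `it_ms`, `rt_ms`, `md_time_ms`,
#'   `md`, `auc`, `x_flip`, `y_flip`, `v_x`, `v_y`, `a_x`, `a_y`.
#' @export
trial_features <- function(raw, geometry = default_geometry()) {
  st <- standardize_trial(raw, geometry)
  mdres <- max_deviation(st)
  dplyr::bind_cols(
    tibble(
      it_ms = as.numeric(attr(st, "it_ms")),
      rt_ms = as.numeric(attr(st, "rt_ms")),
      md_time_ms = mdres$md_time_ms,
      md = mdres$md,
      auc = area_under_curve(st),
      x_flip = count_flips(st, "x"),
      y_flip = count_flips(st, "y")
    ),
    frame_kinematics(st)
  )
}

#' Per-trial metrics for every trajectory of a cohort
#'
#' @param cohort A cohort object from [generate_cohort()] (or a list with a
#'   long `trajectories` tibble).
#' @param geometry Screen geometry used when the cohort was recorded.
#' @return A tibble with one row per (participant, question) and all
#'   [trial_features()] columns.
#' @export
extract_trial_features <- function(cohort, geometry = NULL) {
  geometry <- geometry %||% cohort$config$geometry %||% default_geometry()
  traj <- cohort$trajectories
  if (is.null(traj) || nrow(traj) == 0) {
    abort("cohort carries no trajectories (generated with trajectories = FALSE?)")
  }
  traj %>%
    group_by(.data$participant_id, .data$question_id) %>%
    dplyr::group_modify(~ trial_features(.x, geometry = geometry)) %>%
    ungroup()
}

#' Average standardized trajectory per group
#'
#' Frame-wise mean of standardized (mirrored) coordinates across all trials
#' of each group, the quantity displayed in average-trajectory plots.
#'
#' @inheritParams extract_trial_features
#' @return A tibble `group`, `frame`, `x`, `y` (101 frames per group).
#' @export
average_trajectory <- function(cohort, geometry = NULL) {
  geometry <- geometry %||% cohort$config$geometry %||% default_geometry()
  traj <- cohort$trajectories
  if (is.null(traj) || nrow(traj) == 0) abort("cohort carries no trajectories")
  paths <- traj %>%
    dplyr::inner_join(cohort$participants, by = "participant_id") %>%
    group_by(.data$group, .data$participant_id, .data$question_id) %>%
    dplyr::group_modify(function(d, key) {
      st <- standardize_trial(d, geometry)
      tibble(frame = st$frame, x = st$x, y = st$y)
    }) %>%
    ungroup()
  if (nrow(paths) == 0) abort("no trajectories to average")
  paths %>%
    group_by(.data$group, .data$frame) %>%
    summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
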