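## Scripted tip steering: waypoint trajectories, interpolation, maneuver
## generators and the pull-curve extractor.

#' Scripted tip trajectory
#'
#' An ordered list of timed waypoints for the handle-layer command position.
#' Times are in MTS cycles. Between waypoints the command either holds the
#' last waypoint (`"hold"`) or interpolates linearly (`"linear"`); past the
#' last waypoint it holds the final position. `max_step` is the quasi-static
#' guard: the runner never moves the handle anchors by more than this per
#' cycle (excess motion is clamped and counted).
#'
#' @param waypoints data.frame with columns `t` (cycles, strictly
#'   increasing, finite), `x`, `y`, `z` (A).
#' @param mode interpolation mode, `"hold"` or `"linear"`.
#' @param max_step quasi-static guard in A per cycle (default 0.02).
#' @return object of class `tip_trajectory`.
#' @export
tip_trajectory <- function(waypoints, mode = c("linear", "hold"),
                           max_step = 0.02) {
  mode <- match.arg(mode)
  waypoints <- as.data.frame(waypoints)
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(waypoints)))
    .stop_cond("steermd_bad_trajectory", "waypoints need columns t, x, y, z")
  if (nrow(waypoints) == 0)
    .stop_cond("steermd_bad_trajectory", "trajectory must be non-empty")
  if (any(!is.finite(as.matrix(waypoints[need]))))
    .stop_cond("steermd_bad_trajectory", "non-finite waypoint")
  if (nrow(waypoints) > 1 && any(diff(waypoints$t) <= 0))
    .stop_cond("steermd_bad_trajectory", "waypoint times must be strictly increasing")
  structure(list(waypoints = waypoints[need], mode = mode,
                 max_step = max_step),
            class = "tip_trajectory")
}

#' @export
print.tip_trajectory <- function(x, ...) {
  cat(sprintf("tip_trajectory: %d waypoints over %g cycles (%s, guard %.3f A/cycle)\n",
              nrow(x$waypoints), max(x$waypoints$t) - min(x$waypoints$t),
              x$mode, x$max_step))
  invisible(x)
}

#' Interpolated steering command at a cycle
#'
#' @param trajectory a [tip_trajectory()].
#' @param cycle cycle index (numeric).
#' @return numeric `c(x, y, z)`.
#' @export
next_command <- function(trajectory, cycle) {
  wp <- trajectory$waypoints
  if (nrow(wp) == 1 || cycle >= max(wp$t))
    return(unlist(wp[nrow(wp), c("x", "y", "z")], use.names = FALSE))
  if (cycle <= wp$t[1])
    return(unlist(wp[1, c("x", "y", "z")], use.names = FALSE))
  if (trajectory$mode == "hold") {
    i <- max(which(wp$t <= cycle))
    return(unlist(wp[i, c("x", "y", "z")], use.names = FALSE))
  }
  vapply(c("x", "y", "z"), function(cc)
    stats::approx(wp$t, wp[[cc]], xout = cycle, rule = 2)$y, numeric(1),
    USE.NAMES = FALSE)
}

#' Maneuver generators: drag, lift, hold
#'
#' Build waypoint sequences whose per-cycle displacement respects the
#' quasi-static guard: `make_drag` moves the command from `start` to `end`
#' at `speed` A per cycle, `make_lift` moves it vertically upward by
#' `height`, `make_hold` holds a position for `cycles` cycles. Sequences
#' compose with [concat_trajectories()].
#'
#' @param start,end command positions `c(x, y, z)` (A).
#' @param speed commanded speed in A per cycle (> 0, and at most
#'   `max_step`).
#' @param height lift height in A (>= 0).
#' @param cycles hold duration.
#' @param t0 start time (cycles) of the first waypoint.
#' @param max_step quasi-static guard passed to [tip_trajectory()].
#' @return a [tip_trajectory()].
#' @export
make_drag <- function(start, end, speed, t0 = 0, max_step = 0.02) {
  if (speed <= 0) .stop_cond("steermd_bad_trajectory", "speed must be > 0")
  dist <- sqrt(sum((end - start)^2))
  if (dist == 0)
    return(tip_trajectory(data.frame(t = t0, x = start[1], y = start[2],
                                     z = start[3]), max_step = max_step))
  n <- ceiling(dist / min(speed, max_step))
  fr <- seq(0, 1, length.out = n + 1)
  tip_trajectory(data.frame(t = t0 + seq(0, n),
                            x = start[1] + fr * (end[1] - start[1]),
                            y = start[2] + fr * (end[2] - start[2]),
                            z = start[3] + fr * (end[3] - start[3])),
                 max_step = max_step)
}

#' @rdname make_drag
#' @export
make_lift <- function(start, height, speed, t0 = 0, max_step = 0.02) {
  if (height < 0) .stop_cond("steermd_bad_trajectory", "height must be >= 0")
  make_drag(start, start + c(0, 0, height), speed, t0 = t0, max_step = max_step)
}

#' @rdname make_drag
#' @export
make_hold <- function(start, cycles, t0 = 0, max_step = 0.02) {
  start <- unname(start)
  tip_trajectory(data.frame(t = c(t0, t0 + cycles), x = start[1],
                            y = start[2], z = start[3]), max_step = max_step)
}

#' Concatenate trajectories in time
#'
#' Each subsequent trajectory's waypoints are shifted to start one cycle
#' after the previous one ends. Guards are inherited from the first.
#'
#' @param ... `tip_trajectory` objects.
#' @return a combined [tip_trajectory()].
#' @export
concat_trajectories <- function(...) {
  trs <- list(...)
  wp <- trs[[1]]$waypoints
  for (tr in trs[-1]) {
    w <- tr$waypoints
    w$t <- w$t - w$t[1] + wp$t[nrow(wp)] + 1
    wp <- rbind(wp, w)
  }
  tip_trajectory(wp, mode = trs[[1]]$mode, max_step = trs[[1]]$max_step)
}

#' Extract the pull curve from run diagnostics
#'
#' One row per cycle: commanded tip height, minimum anchoring-atom-to-tip
#' distance and the vertical restraint force on the handle layer. The force
#' is the sum of the harmonic anchor forces acting on the handle atoms; a
#' negative value means the tip assembly is being pulled down (toward the
#' sample), i.e. the junction is under tension during a lift.
#'
#' @param diag diagnostics data.frame from [run_cycles()].
#' @param file optional CSV path to write.
#' @return data.frame with `cycle`, `tip_z`, `anchor_dist`, `force_z`.
#' @export
record_pull_curve <- function(diag, file = NULL) {
  out <- data.frame(cycle = diag$cycle, tip_z = diag$tip_cmd_z,
                    anchor_dist = diag$min_anchor_dist,
                    force_z = diag$handle_fz)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
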