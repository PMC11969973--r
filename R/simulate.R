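# Forward simulation: fixed-step RK4 of the coupled neural +
# musculoskeletal system (compiled engine), fall detection, trajectory
# recording, and gait-metric extraction.

#' Run a gait simulation
#'
#' Integrates the full model with the fourth-order Runge-Kutta method at
#' the configured step (default 0.1 ms) for the configured duration
#' (default 15 s), recording the state at the decimated rate (default
#' 100 Hz). The run terminates normally at a fall (hip below the
#' configured fraction of standing height, or HAT pitch beyond the
#' configured bound); the fall time is recorded. The simulation contains
#' no randomness: identical inputs give bitwise-identical trajectories.
#'
#' @param theta Free-parameter vector (length 49).
#' @param s_ppn,s_cnf Higher-center command intensities applied during the
#'   first 3 s (both 1 reproduces the unmodified command).
#' @param config A `fogsim_config`.
#' @param duration Override of `config$sim$duration` (s).
#' @param state0 Optional initial state (length 45); default standing.
#' @return An object of class `fogsim_trajectory`: list with `t`, `state`
#'   (samples x 45), `grf` (x 2), `alpha` (x 18), `fall_time` (NA if the
#'   model never fell), `config`, `theta`, `s_ppn`, `s_cnf`.
#' @export
run_gait <- function(theta, s_ppn = 1, s_cnf = 1,
                     config = default_parameters(),
                     duration = config$sim$duration,
                     state0 = initial_state(config)) {
  stopifnot(length(theta) == n_free_parameters())
  sp <- standing_posture(config)
  res <- .run_gait_cpp(state0, as.numeric(theta), s_ppn, s_cnf,
                       config$sim$dt, duration, config$sim$decimation,
                       config$sim$fall_hip_fraction * sp$standing_hip_height,
                       config$sim$fall_pitch, config)
  structure(list(t = res$t, state = res$state, grf = res$grf,
                 alpha = res$alpha,
                 fall_time = if (is.na(res$fall_time)) NA_real_
                             else res$fall_time,
                 aborted = res$aborted,
                 duration = duration, config = config, theta = theta,
                 s_ppn = s_ppn, s_cnf = s_cnf),
            class = "fogsim_trajectory")
}

#' @export
print.fogsim_trajectory <- function(x, ...) {
  gm <- gait_metrics(x)
  cat(sprintf("fogsim trajectory: %.1f s recorded at %d samples\n",
              max(x$t), length(x$t)))
  cat(sprintf("  command (s_ppn, s_cnf) = (%.2f, %.2f)\n", x$s_ppn, x$s_cnf))
  if (gm$fell) cat(sprintf("  fell at t = %.2f s\n", x$fall_time))
  cat(sprintf("  distance %.2f m, %d steps, speed %.2f m/s\n",
              gm$D, gm$S, gm$V))
  invisible(x)
}

#' Lower-leg signals of a trajectory
#'
#' The freezing-of-gait detector consumes the anteroposterior
#' acceleration of each lower leg (second central difference of the shank
#' midpoint x-position on the decimated series) and each shank's angular
#' velocity.
#'
#' @param traj A `fogsim_trajectory`.
#' @return Data frame: t, accel_left, accel_right, omega_left,
#'   omega_right.
#' @export
leg_signals <- function(traj) {
  st <- traj$state
  sg <- traj$config$body$segments
  midx <- function(thi, shi)
    st[, 1] + sg$thigh$length * sin(st[, thi]) +
      0.5 * sg$shank$length * sin(st[, shi])
  n <- length(traj$t)
  accel <- function(x) {
    if (n < 3) return(rep(0, n))
    h <- traj$t[2] - traj$t[1]
    a <- c(0, diff(x, differences = 2) / h^2, 0)
    a[1] <- a[2]; a[n] <- a[n - 1]
    a
  }
  data.frame(t = traj$t,
             accel_left = accel(midx(4, 5)),
             accel_right = accel(midx(7, 8)),
             omega_left = st[, 14],
             omega_right = st[, 17])
}

#' Detect step events from the ground-reaction forces
#'
#' A step event is a vertical-GRF onset: the force rising through a small
#' threshold after the foot has been unloaded for at least the refractory
#' time, and staying loaded for at least the refractory time (so brief
#' force spikes are debounced in either direction).
#'
#' @param traj A `fogsim_trajectory`, or a list with `t` and a
#'   two-column `grf` matrix.
#' @param threshold Onset force (N).
#' @param refractory Minimum unloaded time before, and loaded time after,
#'   an onset (s).
#' @return Data frame: `time`, `side` ("left"/"right").
#' @export
detect_steps <- function(traj,
                         threshold = traj$config$sim$step_force_threshold,
                         refractory = traj$config$sim$step_refractory) {
  t <- traj$t; grf <- traj$grf
  dt <- stats::median(diff(t))
  out <- list()
  for (s in 1:2) {
    loaded <- grf[, s] > threshold
    r <- rle(loaded)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    times <- numeric(0)
    for (j in seq_along(r$values)) {
      if (!r$values[j] || j == 1) next  # initial loading is not a step
      dur_loaded <- r$lengths[j] * dt
      dur_unloaded <- r$lengths[j - 1] * dt
      if (dur_loaded >= refractory && dur_unloaded >= refractory)
        times <- c(times, t[starts[j]])
    }
    out[[s]] <- if (length(times))
      data.frame(time = times, side = c("left", "right")[s]) else NULL
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) return(data.frame(time = numeric(0), side = character(0)))
  ev[order(ev$time), , drop = FALSE]
}

#' Gait summary metrics
#'
#' Walked distance D (hip x-displacement until the fall or the end of the
#' run), step count S, locomotion duration T, mean speed V = D/T, and the
#' gross metabolic cost of transport
#' \deqn{C = \frac{1}{T M V} \int_0^T \sum_m \dot E_m \, dt,}
#' where M is total body mass. C is reported as NA when T or V is zero
#' (not infinity). `D3` is the displacement over the first 3 s, the
#' quantity compared across freezing clusters.
#'
#' @param traj A `fogsim_trajectory`.
#' @return List of class `fogsim_metrics`: D, S, T, V, C, D3, fell.
#' @export
gait_metrics <- function(traj) {
  t <- traj$t; st <- traj$state
  fell <- !is.na(traj$fall_time)
  T_loc <- if (fell) traj$fall_time else traj$duration
  x0 <- st[1, 1]
  D <- st[nrow(st), 1] - x0
  i3 <- which(t <= 3)
  D3 <- if (length(i3)) st[max(i3), 1] - x0 else 0
  S <- nrow(detect_steps(traj))
  V <- if (T_loc > 0) D / T_loc else 0
  Etot <- st[nrow(st), 45]
  M <- traj$config$body$total_mass
  C <- if (T_loc > 0 && V > 0) Etot / (T_loc * M * V) else NA_real_
  structure(list(D = D, S = S, T = T_loc, V = V, C = C, D3 = D3,
                 fell = fell),
            class = "fogsim_metrics")
}

#' @export
print.fogsim_metrics <- function(x, ...) {
  cat(sprintf("D = %.2f m, S = %d, T = %.2f s, V = %.2f m/s, C = %s, %s\n",
              x$D, x$S, x$T, x$V,
              if (is.na(x$C)) "NA" else sprintf("%.2f", x$C),
              if (x$fell) "fell" else "no fall"))
  invisible(x)
}

#' Stick-figure plot of a trajectory
#'
#' Draws the 7-link body at regularly spaced times along the run (base
#' graphics); inspection aid only.
#'
#' @param traj A `fogsim_trajectory`.
#' @param n_frames Number of frames to draw.
#' @param ... Passed to `plot()`.
#' @return Invisibly, the frame times.
#' @export
plot_stick <- function(traj, n_frames = 12, ...) {
  sg <- traj$config$body$segments; fg <- traj$config$body$foot_geom
  idx <- unique(round(seq(1, nrow(traj$state), length.out = n_frames)))
  xr <- range(traj$state[idx, 1]) + c(-0.6, 0.6)
  plot(NA, xlim = xr, ylim = c(-0.05, 1.8), asp = 1,
       xlab = "x (m)", ylab = "y (m)", ...)
  graphics::abline(h = 0, col = "grey70")
  for (i in idx) {
    q <- traj$state[i, 1:9]
    hip <- q[1:2]
    top <- hip + sg$hat$length * c(-sin(q[3]), cos(q[3]))
    col <- grDevices::grey(0.8 - 0.6 * i / max(idx))
    graphics::segments(hip[1], hip[2], top[1], top[2], col = col, lwd = 2)
    for (s in 0:1) {
      it <- 4 + 3 * s; is <- 5 + 3 * s; ifo <- 6 + 3 * s
      knee <- hip + sg$thigh$length * c(sin(q[it]), -cos(q[it]))
      ank <- knee + sg$shank$length * c(sin(q[is]), -cos(q[is]))
      rot <- function(v) c(cos(q[ifo]) * v[1] - sin(q[ifo]) * v[2],
                           sin(q[ifo]) * v[1] + cos(q[ifo]) * v[2])
      heel <- ank + rot(c(-fg$heel_back, -fg$ankle_height))
      toe <- ank + rot(c(fg$toe_front, -fg$ankle_height))
      xs <- c(hip[1], knee[1], ank[1], heel[1], toe[1])
      ys <- c(hip[2], knee[2], ank[2], heel[2], toe[2])
      graphics::lines(xs[1:3], ys[1:3], col = col, lwd = 1.5)
      graphics::lines(xs[c(4, 5)], ys[c(4, 5)], col = col, lwd = 1.5)
      graphics::segments(ank[1], ank[2], heel[1], heel[2], col = col)
    }
  }
  invisible(traj$t[idx])
}

#' Export a trajectory as tidy CSV plus a JSON metrics sidecar
#'
#' @param traj A `fogsim_trajectory`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
export_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- leg_signals(traj)
  df <- data.frame(t = traj$t,
                   x_hip = traj$state[, 1], y_hip = traj$state[, 2],
                   pitch = traj$state[, 3],
                   grf_left = traj$grf[, 1], grf_right = traj$grf[, 2],
                   sig[, -1])
  csv <- file.path(dir, "trajectory.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  js <- file.path(dir, "metrics.json")
  gm <- gait_metrics(traj)
  jsonlite::write_json(unclass(gm), js, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv, js))
}
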