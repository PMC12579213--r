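## Trajectory-level migration statistics. A trajectory is a data.frame with
## columns cell_id, frame, t_min, x_um, y_um, uniformly spaced in time.

check_trajectory <- function(traj) {
  stopifnot(all(c("t_min", "x_um", "y_um") %in% names(traj)))
  if (nrow(traj) < 2) stop("trajectory needs at least 2 points")
  dt <- diff(traj$t_min)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-8 * max(dt[1], 1)) {
    stop("trajectory must have uniform time spacing")
  }
  invisible(dt[1])
}

#' Path-level speed and directionality of a trajectory
#'
#' `total_path_len` is the summed segment length, `displacement` the
#' start-to-end distance, `directionality = displacement / total_path_len`
#' (1 for a straight co-directed path), and
#' `speed = total_path_len / elapsed time`.
#'
#' @param traj Trajectory data.frame (`t_min`, `x_um`, `y_um`).
#' @return List with `total_path_len`, `displacement`, `directionality`,
#'   `speed` (micrometres / minute).
#' @examples
#' tr <- make_trajectory(50, turn_sd_deg = 0, seed = 1)$trajectory
#' path_stats(tr)$directionality
#' @export
path_stats <- function(traj) {
  check_trajectory(traj)
  seg <- sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2)
  total <- sum(seg)
  disp <- sqrt((traj$x_um[nrow(traj)] - traj$x_um[1])^2 +
               (traj$y_um[nrow(traj)] - traj$y_um[1])^2)
  if (total == 0) stop("undefined value: zero total path length")
  list(total_path_len = total, displacement = disp,
       directionality = disp / total,
       speed = total / (traj$t_min[nrow(traj)] - traj$t_min[1]))
}

#' Turning angle between two movement vectors
#'
#' The angle between a previous movement (or retraction) vector and a new
#' protrusion vector: `theta = arccos(a.b / (|a| |b|))` in degrees,
#' `[0, 180]`. The cosine is clamped to `[-1, 1]` before `acos` to absorb
#' floating-point overflow.
#'
#' @param a_vec,b_vec Nonzero numeric 2-vectors.
#' @return List with `a_vec`, `b_vec`, `theta_deg`.
#' @examples
#' turning_angle(c(1, 0), c(0, 1))$theta_deg  # 90
#' @export
turning_angle <- function(a_vec, b_vec) {
  na <- sqrt(sum(a_vec^2)); nb <- sqrt(sum(b_vec^2))
  if (na == 0 || nb == 0) stop("undefined value: zero-length vector")
  cosv <- sum(a_vec * b_vec) / (na * nb)
  list(a_vec = a_vec, b_vec = b_vec,
       theta_deg = rad2deg(acos(pmin(1, pmax(-1, cosv)))))
}

#' Six-frame windowed cell speed at a frame
#'
#' Mean step length over the six steps surrounding frame `t`:
#' `Speed(t) = sum_{k=-2..3} |C_{t+k} - C_{t+k-1}| / 6`, defined for
#' 0-based frames `3 <= t <= T - 3` of a `T + 1`-point trajectory.
#'
#' @param traj Trajectory data.frame.
#' @param t 0-based frame index.
#' @return Speed in position units per frame.
#' @export
windowed_speed <- function(traj, t) {
  n <- nrow(traj)
  if (t < 3 || t > (n - 1) - 3) stop("bounds error: t outside [3, T-3]")
  i <- t + 1  # 1-based row of frame t
  ks <- -2:3
  steps <- sqrt((traj$x_um[i + ks] - traj$x_um[i + ks - 1])^2 +
                (traj$y_um[i + ks] - traj$y_um[i + ks - 1])^2)
  sum(steps) / 6
}

#' Six-frame windowed moving direction at a frame
#'
#' `Direction(t) = sum_{k=-2..3} (C_{t+k} - C_{t+k-1}) / 6`, which
#' telescopes to `(C_{t+3} - C_{t-3}) / 6`. Same validity window as
#' [windowed_speed()].
#'
#' @inheritParams windowed_speed
#' @return Numeric 2-vector `(dx, dy)` in position units per frame.
#' @export
windowed_direction <- function(traj, t) {
  n <- nrow(traj)
  if (t < 3 || t > (n - 1) - 3) stop("bounds error: t outside [3, T-3]")
  i <- t + 1
  c((traj$x_um[i + 3] - traj$x_um[i - 3]) / 6,
    (traj$y_um[i + 3] - traj$y_um[i - 3]) / 6)
}

# Nearest-frame resampling of a trajectory onto a coarser uniform grid.
resample_trajectory <- function(traj, dt_min) {
  native <- check_trajectory(traj)
  if (abs(native - dt_min) < 1e-9) return(traj)
  grid <- seq(traj$t_min[1], traj$t_min[nrow(traj)], by = dt_min)
  idx <- vapply(grid, function(g) which.min(abs(traj$t_min - g)), integer(1))
  out <- traj[idx, , drop = FALSE]
  out$t_min <- grid
  rownames(out) <- NULL
  out
}

#' Directional autocorrelation of migration trajectories
#'
#' For each lag `L` (a multiple of the step `dt_min`), the mean cosine of
#' the angle between displacement vectors `C_{t+dt} - C_t` and
#' `C_{t+L+dt} - C_{t+L}`, pooled over all valid overlapping pairs of all
#' cells. Zero-length displacement steps are excluded. Value at lag 0 is 1
#' by construction.
#'
#' @param trajs A trajectory data.frame or a list of them.
#' @param max_lag_min Largest lag in minutes.
#' @param dt_min Displacement time step in minutes (default 10);
#'   trajectories on a finer grid are resampled by nearest frame.
#' @return Data.frame with `lag_min`, `mean_cos`, `n_pairs`.
#' @examples
#' tr <- make_trajectory(200, turn_sd_deg = 30, seed = 1)$trajectory
#' head(direction_autocorrelation(tr, max_lag_min = 60))
#' @export
direction_autocorrelation <- function(trajs, max_lag_min, dt_min = 10) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  trajs <- lapply(trajs, resample_trajectory, dt_min = dt_min)
  lags <- seq(0, max_lag_min, by = dt_min)
  sums <- numeric(length(lags)); counts <- integer(length(lags))
  any_step <- FALSE
  for (tr in trajs) {
    dx <- diff(tr$x_um); dy <- diff(tr$y_um)
    len <- sqrt(dx^2 + dy^2)
    ok <- len > 0
    if (any(ok)) any_step <- TRUE
    n <- length(dx)
    for (li in seq_along(lags)) {
      s <- as.integer(round(lags[li] / dt_min))
      if (n - s < 1) next
      i <- seq_len(n - s)
      valid <- ok[i] & ok[i + s]
      if (!any(valid)) next
      cosv <- (dx[i] * dx[i + s] + dy[i] * dy[i + s]) /
        (len[i] * len[i + s])
      sums[li] <- sums[li] + sum(cosv[valid])
      counts[li] <- counts[li] + sum(valid)
    }
  }
  if (!any_step) stop("undefined value: all displacement steps are zero")
  data.frame(lag_min = lags,
             mean_cos = ifelse(counts > 0, sums / counts, NA_real_),
             n_pairs = counts)
}
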