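#' DISC trajectory of one deployment
#'
#' Positions of a single larva in the chamber arena, camera frame of
#' reference: origin at the arena center, `y_cm` toward the camera-frame
#' "up", units cm. The default arena is 20 cm in diameter (radius 10 cm) and
#' each deployment starts with an acclimation interval that is discarded
#' before analysis (default 300 s).
#'
#' @param deployment_id Identifier of the deployment.
#' @param t_s Timestamps, seconds from acquisition start, strictly
#'   increasing.
#' @param x_cm,y_cm Larva position, cm from arena center.
#' @param arena_radius_cm Physical arena radius, cm.
#' @param acclimation_s Leading interval to discard before analysis, s.
#' @param wall_tol_cm Tolerance beyond the wall allowed before positions are
#'   rejected as implausible (digitization jitter).
#' @return A `disc_trajectory`: list with the fields above.
#' @export
trajectory <- function(deployment_id, t_s, x_cm, y_cm,
                       arena_radius_cm = 10, acclimation_s = 300,
                       wall_tol_cm = 0.5) {
  n <- length(t_s)
  if (n < 1 || length(x_cm) != n || length(y_cm) != n) {
    stop("trajectory: t_s, x_cm, y_cm must have equal positive length")
  }
  if (anyNA(t_s) || anyNA(x_cm) || anyNA(y_cm)) {
    stop("trajectory: missing values in positions or timestamps")
  }
  if (n > 1 && any(diff(t_s) <= 0)) {
    stop("trajectory: timestamps must be strictly increasing")
  }
  rad <- sqrt(x_cm^2 + y_cm^2)
  if (any(rad > arena_radius_cm + wall_tol_cm)) {
    stop(sprintf(
      "trajectory '%s': %d position(s) outside the %.1f cm arena radius",
      deployment_id, sum(rad > arena_radius_cm + wall_tol_cm), arena_radius_cm
    ))
  }
  structure(
    list(
      deployment_id = as.character(deployment_id)[1],
      t_s = as.numeric(t_s), x_cm = as.numeric(x_cm), y_cm = as.numeric(y_cm),
      arena_radius_cm = arena_radius_cm, acclimation_s = acclimation_s
    ),
    class = "disc_trajectory"
  )
}

#' @export
print.disc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<disc_trajectory> '%s': %d points over %.1f s (arena radius %.1f cm)\n",
    x$deployment_id, length(x$t_s), diff(range(x$t_s)), x$arena_radius_cm
  ))
  invisible(x)
}

#' Subsample a trajectory to 1 Hz
#'
#' Removes the acclimation window and keeps one position per whole second:
#' at each 1 s tick the nearest recorded frame at or before the tick. A track
#' already sampled at exactly 1 Hz passes through unchanged.
#'
#' @param raw A [trajectory()] at arbitrary frame rate (>= 2 points).
#' @return A `disc_trajectory` with one point per second and
#'   `acclimation_s = 0`.
#' @export
subsample_1hz <- function(raw) {
  stopifnot(inherits(raw, "disc_trajectory"))
  keep <- raw$t_s >= raw$acclimation_s
  t <- raw$t_s[keep]
  if (length(t) < 2 || diff(range(t)) < 1) {
    stop(sprintf(
      "subsample_1hz '%s': < 2 s of data after removing the %.0f s acclimation window",
      raw$deployment_id, raw$acclimation_s
    ))
  }
  ticks <- seq(ceiling(t[1]), floor(t[length(t)]))
  if (length(ticks) < 2) {
    stop(sprintf("subsample_1hz '%s': < 2 s of coverage", raw$deployment_id))
  }
  idx <- findInterval(ticks, t)  # last frame at or before each tick
  trajectory(raw$deployment_id, ticks, raw$x_cm[keep][idx], raw$y_cm[keep][idx],
             arena_radius_cm = raw$arena_radius_cm, acclimation_s = 0)
}

#' Instantaneous swimming speeds
#'
#' Euclidean displacement between consecutive retained positions divided by
#' the time step, cm/s. For a 1 Hz track of n points this yields n - 1
#' speeds.
#'
#' @param traj A [trajectory()] with >= 2 points.
#' @return Numeric vector of speeds, cm/s, length `n - 1`.
#' @export
instantaneous_speeds <- function(traj) {
  stopifnot(inherits(traj, "disc_trajectory"))
  if (length(traj$t_s) < 2) stop("instantaneous_speeds: need >= 2 points")
  sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2) / diff(traj$t_s)
}

#' Turning angles along a trajectory
#'
#' For each interior point, the absolute angle between the incoming and
#' outgoing displacement vectors (the angle produced by three successive
#' points): 0 for straight-line motion, up to 180 for full reversals.
#' Zero-length displacements carry no direction and are skipped; the number
#' skipped is attached as attribute `n_zero_steps`.
#'
#' @param traj A [trajectory()] with >= 3 points.
#' @return Numeric vector of unsigned turning angles in `[0, 180]` degrees
#'   (length `n - 2` when no steps are degenerate), with attribute
#'   `n_zero_steps`. All displacements zero yields an empty vector.
#' @export
turning_angles <- function(traj) {
  stopifnot(inherits(traj, "disc_trajectory"))
  if (length(traj$t_s) < 3) stop("turning_angles: need >= 3 points")
  dx <- diff(traj$x_cm)
  dy <- diff(traj$y_cm)
  moving <- dx != 0 | dy != 0
  n_zero <- sum(!moving)
  if (!any(moving)) {
    warning(sprintf("turning_angles '%s': larva never moved", traj$deployment_id))
    return(structure(numeric(0), n_zero_steps = n_zero))
  }
  h <- atan2(dx[moving], dy[moving])  # headings of non-degenerate steps
  turn <- abs((rad2deg(diff(h)) + 180) %% 360 - 180)
  structure(turn, n_zero_steps = n_zero)
}

#' Position bearings from the arena center
#'
#' The compass-style bearing of each recorded position as seen from the
#' arena center, in the camera frame: degrees clockwise from the frame "up"
#' axis, so (0, 5) maps to 0 and (5, 0) to 90. These position bearings — not
#' instantaneous headings — are the angles entering the Rayleigh test of a
#' deployment. Positions closer to the center than `center_cutoff_cm` have
#' ill-conditioned bearings and are excluded (count in attribute
#' `n_center_excluded`).
#'
#' @param traj A [trajectory()].
#' @param center_cutoff_cm Exclusion radius around the arena center, cm.
#' @return An [angle_sample()] with attribute `n_center_excluded`.
#' @export
position_bearings <- function(traj, center_cutoff_cm = 0.5) {
  stopifnot(inherits(traj, "disc_trajectory"))
  rad <- sqrt(traj$x_cm^2 + traj$y_cm^2)
  keep <- rad >= center_cutoff_cm
  if (!any(keep)) {
    stop(sprintf(
      "position_bearings '%s': all positions within %.2f cm of the arena center",
      traj$deployment_id, center_cutoff_cm
    ))
  }
  s <- angle_sample(rad2deg(atan2(traj$x_cm[keep], traj$y_cm[keep])) %% 360,
                    label = traj$deployment_id)
  attr(s, "n_center_excluded") <- sum(!keep)
  attr(s, "t_s") <- traj$t_s[keep]
  s
}

#' Per-deployment kinematics summary
#'
#' Mean instantaneous speed and mean unsigned turning angle of a (1 Hz)
#' trajectory, with the number of retained samples.
#'
#' @param traj A [trajectory()], normally the output of [subsample_1hz()].
#' @return List with `mean_speed_cm_s`, `mean_turning_deg`, `n_points`.
#' @export
kinematics_summary <- function(traj) {
  turns <- turning_angles(traj)
  list(
    mean_speed_cm_s = mean(instantaneous_speeds(traj)),
    mean_turning_deg = if (length(turns)) mean(turns) else NA_real_,
    n_points = length(traj$t_s)
  )
}

#' Convert pixel coordinates to cm using the arena extent
#'
#' Digitized positions are often in pixels. Given the known physical arena
#' diameter and the pixel extent the arena spans in the video, this rescales
#' and re-centers coordinates so the arena center is the origin.
#'
#' @param x_px,y_px Pixel coordinates.
#' @param arena_diameter_px Arena diameter in pixels as detected in the video.
#' @param center_px Pixel coordinates of the arena center (length 2);
#'   defaults to the midpoint of the observed x/y ranges.
#' @param arena_diameter_cm Physical arena diameter, cm.
#' @return A list with `x_cm` and `y_cm`.
#' @export
pixels_to_cm <- function(x_px, y_px, arena_diameter_px,
                         center_px = NULL, arena_diameter_cm = 20) {
  stopifnot(arena_diameter_px > 0)
  if (is.null(center_px)) {
    center_px <- c(mean(range(x_px)), mean(range(y_px)))
  }
  scale <- arena_diameter_cm / arena_diameter_px
  list(x_cm = (x_px - center_px[1]) * scale,
       y_cm = (y_px - center_px[2]) * scale)
}

#' Read deployment trajectories from CSV
#'
#' Expects a header with columns `deployment_id, t_s, x_cm, y_cm` (UTF-8,
#' '.' decimal). Returns one [trajectory()] per deployment id.
#'
#' @param path CSV file path.
#' @param arena_radius_cm,acclimation_s Passed to [trajectory()].
#' @return Named list of `disc_trajectory` objects.
#' @export
read_trajectories_csv <- function(path, arena_radius_cm = 10,
                                  acclimation_s = 300) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("deployment_id", "t_s", "x_cm", "y_cm")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("read_trajectories_csv: '%s' lacks column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  out <- lapply(split(d, d$deployment_id), function(g) {
    g <- g[order(g$t_s), ]
    trajectory(g$deployment_id[1], g$t_s, g$x_cm, g$y_cm,
               arena_radius_cm = arena_radius_cm,
               acclimation_s = acclimation_s)
  })
  out[order(names(out))]
}
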