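#' Chamber compass series
#'
#' Heading of the rotating chamber over a deployment: at each time the
#' compass bearing (degrees clockwise from north) that the camera-frame "up"
#' axis points to. Adding the heading to a camera-frame bearing yields the
#' cardinal-frame bearing (see [rotate_to_cardinal()] for the sign
#' convention).
#'
#' @param t_s Timestamps, seconds from acquisition start, strictly
#'   increasing.
#' @param heading_deg Chamber headings, degrees clockwise from north.
#' @return A `compass_series` list with `t_s` and `heading_deg` (canonical).
#' @export
compass_series <- function(t_s, heading_deg) {
  n <- length(t_s)
  if (n < 1 || length(heading_deg) != n) {
    stop("compass_series: t_s and heading_deg must have equal positive length")
  }
  if (anyNA(t_s) || anyNA(heading_deg)) stop("compass_series: missing values")
  if (n > 1 && any(diff(t_s) <= 0)) {
    stop("compass_series: timestamps must be strictly increasing")
  }
  structure(list(t_s = as.numeric(t_s), heading_deg = heading_deg %% 360),
            class = "compass_series")
}

#' Merge several compass records into one series
#'
#' The DISC carries several physical compasses; when their synchronized
#' records are available separately this utility fuses them by element-wise
#' circular mean on a common time base.
#'
#' @param compasses List of [compass_series()] sharing identical timestamps.
#' @return A single `compass_series`.
#' @export
merge_compasses <- function(compasses) {
  stopifnot(length(compasses) >= 1)
  t0 <- compasses[[1]]$t_s
  for (cs in compasses) {
    stopifnot(inherits(cs, "compass_series"))
    if (!isTRUE(all.equal(cs$t_s, t0))) {
      stop("merge_compasses: compass series are not on a common time base")
    }
  }
  h <- vapply(seq_along(t0), function(i) {
    m <- circular_mean_and_r(vapply(compasses, function(cs) cs$heading_deg[i],
                                    numeric(1)))
    if (is.na(m$mean_bearing_deg)) {
      stop(sprintf("merge_compasses: compasses cancel at t = %g s", t0[i]))
    }
    m$mean_bearing_deg
  }, numeric(1))
  compass_series(t0, h)
}

# heading at arbitrary times by nearest neighbor; errors on gaps > max_gap_s
heading_at <- function(compass, t_s, max_gap_s = 2) {
  stopifnot(inherits(compass, "compass_series"))
  idx <- findInterval(t_s, compass$t_s, all.inside = FALSE)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(compass$t_s))
  d_lo <- abs(t_s - compass$t_s[lo])
  d_hi <- abs(t_s - compass$t_s[hi])
  nearest <- ifelse(d_hi < d_lo, hi, lo)
  gap <- pmin(d_lo, d_hi)
  if (any(gap > max_gap_s)) {
    bad <- which.max(gap)
    stop(sprintf(
      "compass gap of %.1f s at sample time %.1f s exceeds the %.1f s limit",
      gap[bad], t_s[bad], max_gap_s
    ))
  }
  compass$heading_deg[nearest]
}

#' Rotate camera-frame bearings into the cardinal frame
#'
#' The chamber (and thus the camera frame) rotates slowly as the DISC
#' drifts; the synchronized compass links the two frames. Per timestamp,
#' `cardinal = (camera + rotation_sign * heading) mod 360`. The default
#' `rotation_sign = +1` encodes the convention that the heading is the
#' compass direction of the camera-frame "up" axis; data recorded under the
#' opposite convention can be ingested with `rotation_sign = -1`.
#'
#' @param bearings_camera An [angle_sample()] of camera-frame bearings. If it
#'   lacks a `t_s` attribute (as attached by [position_bearings()]), supply
#'   `t_s` explicitly.
#' @param compass A [compass_series()] covering every bearing timestamp to
#'   within `max_gap_s` (nearest-neighbor lookup).
#' @param t_s Timestamps of the bearings, seconds.
#' @param max_gap_s Largest tolerated distance to the nearest compass
#'   reading, s.
#' @param rotation_sign `+1` or `-1`; see Details.
#' @return An `angle_sample` of cardinal bearings (with `t_s` attribute
#'   preserved).
#' @export
rotate_to_cardinal <- function(bearings_camera, compass,
                               t_s = attr(bearings_camera, "t_s"),
                               max_gap_s = 2, rotation_sign = 1) {
  bearings_camera <- as_angle_sample(bearings_camera)
  stopifnot(rotation_sign %in% c(-1, 1))
  if (is.null(t_s)) stop("rotate_to_cardinal: bearing timestamps required")
  if (length(t_s) != length(bearings_camera$angles_deg)) {
    stop("rotate_to_cardinal: one timestamp per bearing required")
  }
  h <- heading_at(compass, t_s, max_gap_s = max_gap_s)
  out <- angle_sample(
    (bearings_camera$angles_deg + rotation_sign * h) %% 360,
    label = paste0(bearings_camera$label, " [cardinal]")
  )
  attr(out, "t_s") <- t_s
  out
}

#' Classify a deployment: non-oriented, device-biased, or oriented
#'
#' Implements the two-step screening applied to every deployment. First, the
#' Rayleigh test on cardinal-frame position bearings asks whether the larva
#' held a non-random position at all (`p >= alpha` means `non_oriented`).
#' Second, for significant larvae the mean resultant length is compared
#' between the camera and cardinal frames: a larva more concentrated in the
#' rotating camera frame than in the cardinal frame was tracking a chamber
#' feature rather than a compass direction, and is flagged `device_biased`.
#' Remaining larvae are `oriented`. The measure-zero tie
#' `rho_camera == rho_cardinal` counts as oriented.
#'
#' @param traj A raw [trajectory()]; it is 1 Hz-subsampled internally.
#' @param compass A [compass_series()] for the deployment.
#' @param alpha Significance level of the uniformity screen.
#' @param rotation_sign Frame-rotation sign convention, see
#'   [rotate_to_cardinal()].
#' @param center_cutoff_cm Passed to [position_bearings()].
#' @return A `frame_analysis` list: `deployment_id`, `n`, `rho_camera`,
#'   `rho_cardinal`, `bearing_cardinal_deg`, `p_cardinal`, `classification`.
#' @export
classify_deployment <- function(traj, compass, alpha = 0.05,
                                rotation_sign = 1, center_cutoff_cm = 0.5) {
  traj1 <- subsample_1hz(traj)
  cam <- position_bearings(traj1, center_cutoff_cm = center_cutoff_cm)
  card <- rotate_to_cardinal(cam, compass, rotation_sign = rotation_sign)
  rho_camera <- circular_mean_and_r(cam)$r
  rt <- rayleigh_test(card)
  classification <- if (rt$p_value >= alpha) {
    "non_oriented"
  } else if (rho_camera > rt$r) {
    "device_biased"
  } else {
    "oriented"
  }
  structure(
    list(
      deployment_id = traj$deployment_id,
      n = rt$n,
      rho_camera = rho_camera,
      rho_cardinal = rt$r,
      bearing_cardinal_deg = rt$mean_bearing_deg,
      p_cardinal = rt$p_value,
      classification = classification
    ),
    class = "frame_analysis"
  )
}

#' @export
print.frame_analysis <- function(x, ...) {
  cat(sprintf(
    "<frame_analysis> '%s': %s (rho cam %.3f vs card %.3f, p = %.3g, bearing %.1f)\n",
    x$deployment_id, x$classification, x$rho_camera, x$rho_cardinal,
    x$p_cardinal, x$bearing_cardinal_deg
  ))
  invisible(x)
}

#' Read compass series from CSV
#'
#' Expects columns `deployment_id, t_s, heading_deg`.
#'
#' @param path CSV file path.
#' @return Named list of [compass_series()] per deployment id.
#' @export
read_compass_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("deployment_id", "t_s", "heading_deg")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("read_compass_csv: '%s' lacks column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  out <- lapply(split(d, d$deployment_id), function(g) {
    g <- g[order(g$t_s), ]
    compass_series(g$t_s, g$heading_deg)
  })
  out[order(names(out))]
}
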