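#' Angle samples
#'
#' An `angle_sample` holds a set of bearings in degrees clockwise from
#' geographic north, canonicalized to `[0, 360)`, together with a free-text
#' provenance label (deployment id, frame of reference, ...). Bearings follow
#' the compass convention throughout the package: 0 = north, 90 = east.
#'
#' @param angles_deg Numeric vector of bearings, degrees clockwise from north.
#'   Any finite values are accepted and reduced modulo 360.
#' @param label Free-text provenance, e.g. a deployment id.
#' @return An object of class `angle_sample`: a list with elements
#'   `angles_deg` (canonical bearings) and `label`.
#' @examples
#' angle_sample(c(-10, 370, 45))
#' @export
angle_sample <- function(angles_deg, label = "") {
  if (length(angles_deg) < 1L) {
    stop("angle_sample: no data (empty angle vector)")
  }
  angles_deg <- as.numeric(angles_deg)
  if (anyNA(angles_deg) || any(!is.finite(angles_deg))) {
    stop("angle_sample: angles must be finite and non-missing")
  }
  structure(
    list(angles_deg = angles_deg %% 360, label = as.character(label)[1]),
    class = "angle_sample"
  )
}

#' @export
print.angle_sample <- function(x, ...) {
  cat(sprintf(
    "<angle_sample> n = %d%s\n", length(x$angles_deg),
    if (nzchar(x$label)) paste0("  [", x$label, "]") else ""
  ))
  print(utils::head(round(x$angles_deg, 1), 10))
  invisible(x)
}

# accept either an angle_sample or a bare numeric vector of degrees
as_angle_sample <- function(x, label = "") {
  if (inherits(x, "angle_sample")) x else angle_sample(x, label)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# resultant length below which the mean direction is treated as undefined
.r_undefined_tol <- 1e-12

#' Circular mean bearing and mean resultant length
#'
#' Computes the circular mean of a sample of compass bearings as the direction
#' of the mean unit vector, and the mean resultant length `r` (the norm of
#' that mean vector, 0 for a uniform or perfectly balanced sample, 1 for
#' identical bearings). When `r` is numerically zero the mean direction is
#' undefined and reported as `NA`.
#'
#' @param sample An [angle_sample()] or numeric vector of bearings (degrees
#'   clockwise from north).
#' @return A list with `mean_bearing_deg` (degrees CW from north in
#'   `[0, 360)`, `NA` when `r` is 0) and `r` (in `[0, 1]`).
#' @examples
#' circular_mean_and_r(c(0, 90))   # 45 degrees, r = sqrt(2)/2
#' circular_mean_and_r(c(0, 180))  # undefined mean, r = 0
#' @export
circular_mean_and_r <- function(sample) {
  sample <- as_angle_sample(sample)
  a <- deg2rad(sample$angles_deg)
  # compass angles: decompose on (north, east) = (cos, sin); atan2(E, N)
  # returns the bearing directly in compass convention
  e <- mean(sin(a))
  n <- mean(cos(a))
  r <- sqrt(e^2 + n^2)
  r <- min(r, 1)  # guard rounding just above 1
  if (r < .r_undefined_tol) {
    return(list(mean_bearing_deg = NA_real_, r = 0))
  }
  list(mean_bearing_deg = rad2deg(atan2(e, n)) %% 360, r = r)
}

#' Circular standard deviation from the mean resultant length
#'
#' The angular dispersion `sqrt(-2 log r)` in radians, the standard
#' "plus/minus SD" companion of a circular mean. It is strictly decreasing in
#' `r`: 0 when all bearings coincide (`r = 1`) and unbounded as the sample
#' approaches uniformity (`r -> 0`, reported as `Inf` with a warning).
#'
#' @param r Mean resultant length(s) in `[0, 1]`.
#' @return Circular standard deviation(s) in radians.
#' @examples
#' circular_sd(1)     # 0
#' circular_sd(0.31)  # 1.53
#' @export
circular_sd <- function(r) {
  if (anyNA(r) || any(r < 0) || any(r > 1)) {
    stop("circular_sd: r must lie in [0, 1]")
  }
  out <- suppressWarnings(sqrt(-2 * log(r)))
  if (any(r == 0)) {
    warning("circular_sd: r = 0, dispersion is infinite")
    out[r == 0] <- Inf
  }
  out
}

# p-value series approximation for the Rayleigh statistic Z = n r^2
rayleigh_p_value <- function(Z, n) {
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  pmin(pmax(p, 0), 1)
}

#' Rayleigh p-value from summary statistics
#'
#' Recomputes the Rayleigh test of circular uniformity from a sample size and
#' a mean resultant length alone, via the statistic `Z = n r^2` and its
#' standard series approximation to the p-value. Useful for cross-checking
#' published (n, r, p) triples.
#'
#' @param n Sample size (>= 2).
#' @param r Mean resultant length in `[0, 1]`.
#' @return The Rayleigh p-value, clamped to `[0, 1]`.
#' @examples
#' rayleigh_p_from_stats(93, 0.02)  # ~0.96
#' @export
rayleigh_p_from_stats <- function(n, r) {
  if (any(n < 2)) stop("rayleigh_p_from_stats: need n >= 2")
  if (any(r < 0) || any(r > 1)) stop("rayleigh_p_from_stats: r must lie in [0, 1]")
  rayleigh_p_value(n * r^2, n)
}

new_circular_summary <- function(n, mean_bearing_deg, r, p_value) {
  structure(
    list(
      n = as.integer(n),
      mean_bearing_deg = mean_bearing_deg,
      r = r,
      circ_sd_rad = if (r > 0) sqrt(-2 * log(r)) else Inf,
      rayleigh_Z = n * r^2,
      p_value = p_value
    ),
    class = "circular_summary"
  )
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(
    "<circular_summary> n = %d  mean = %s deg  r = %.3f  SD = %.2f rad  Z = %.3f  p = %.3g\n",
    x$n,
    if (is.na(x$mean_bearing_deg)) "undefined" else sprintf("%.1f", x$mean_bearing_deg),
    x$r, x$circ_sd_rad, x$rayleigh_Z, x$p_value
  ))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of bearings departs from circular uniformity using
#' the Rayleigh statistic `Z = n r^2`, where `r` is the mean resultant
#' length. Small p-values indicate concentration around a common direction.
#' In the DISC analysis this is applied to a larva's 1 Hz position bearings
#' to decide whether it kept a non-random position in the arena.
#'
#' @param sample An [angle_sample()] or numeric vector of bearings (degrees
#'   clockwise from north); at least 2 values.
#' @return A `circular_summary`: list with `n`, `mean_bearing_deg`, `r`,
#'   `circ_sd_rad`, `rayleigh_Z` and `p_value`.
#' @seealso [second_order_rayleigh()] for the population-level test on
#'   per-larva mean bearings, [rayleigh_p_from_stats()] for the p-value from
#'   `(n, r)` alone.
#' @examples
#' rayleigh_test(c(10, 20, 15, 5, 12))
#' @export
rayleigh_test <- function(sample) {
  sample <- as_angle_sample(sample)
  n <- length(sample$angles_deg)
  if (n < 2) stop("rayleigh_test: need at least 2 angles")
  m <- circular_mean_and_r(sample)
  new_circular_summary(n, m$mean_bearing_deg, m$r,
                       rayleigh_p_value(n * m$r^2, n))
}

#' Second-order Rayleigh test on per-individual mean bearings
#'
#' Pools the mean bearings of individuals (one bearing per retained larva,
#' each entering as an unweighted unit vector) and applies the Rayleigh test
#' to ask whether the population shares a common direction. The computation
#' is identical to [rayleigh_test()]; the distinct entry point documents the
#' second-order use and keeps provenance explicit.
#'
#' @param mean_bearings An [angle_sample()] or numeric vector of per-larva
#'   mean bearings, degrees clockwise from north; at least 2 values.
#' @return A `circular_summary` (see [rayleigh_test()]).
#' @export
second_order_rayleigh <- function(mean_bearings) {
  rayleigh_test(mean_bearings)
}

#' Bearings relative to per-element reference directions
#'
#' Re-expresses each bearing relative to its own reference direction:
#' `(bearing - reference) mod 360`. A larva swimming exactly toward its
#' reference (e.g. the sun azimuth of its deployment) maps to 0 degrees, so a
#' population tracking a per-deployment cue concentrates near 0 after this
#' transform even when raw cardinal bearings are dispersed.
#'
#' @param bearings An [angle_sample()] or numeric vector of bearings.
#' @param references_deg Reference direction(s), degrees clockwise from
#'   north; either one per bearing or a single common value.
#' @return An `angle_sample` of relative bearings.
#' @examples
#' relative_bearings(c(10), 350)  # 20 (wraparound)
#' @export
relative_bearings <- function(bearings, references_deg) {
  bearings <- as_angle_sample(bearings)
  n <- length(bearings$angles_deg)
  references_deg <- as.numeric(references_deg)
  if (!(length(references_deg) %in% c(1L, n))) {
    stop(sprintf(
      "relative_bearings: %d bearings but %d references",
      n, length(references_deg)
    ))
  }
  if (anyNA(references_deg)) stop("relative_bearings: missing reference direction")
  angle_sample((bearings$angles_deg - references_deg) %% 360,
               label = bearings$label)
}

#' Expected resultant length of a von Mises distribution
#'
#' `A(kappa) = I1(kappa) / I0(kappa)`, the mean resultant length of a von
#' Mises sample in the large-n limit; used to check simulator calibration.
#'
#' @param kappa Concentration parameter, >= 0.
#' @return Expected mean resultant length in `[0, 1)`.
#' @export
von_mises_A <- function(kappa) {
  stopifnot(all(kappa >= 0))
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}
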