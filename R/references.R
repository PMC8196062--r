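#' Solar azimuth at a place and time
#'
#' Computes the compass direction of the sun (degrees clockwise from true
#' north) from a NOAA-style low-precision solar ephemeris (Meeus-class
#' approximation, accurate to well within 0.5 degrees for current decades).
#' The solar elevation is attached as attribute `elevation_deg`; when the
#' sun is below the horizon the azimuth is still returned and the attribute
#' `below_horizon` is set, since a bearing to the sun's compass direction
#' remains defined.
#'
#' @param lat,lon Decimal degrees; south and west negative.
#' @param time_utc A `POSIXct` time (UTC) or anything coercible via
#'   [as.POSIXct()] with `tz = "UTC"`.
#' @return Solar azimuth in `[0, 360)` degrees CW from north, with
#'   attributes `elevation_deg` and `below_horizon`.
#' @examples
#' sun_azimuth(16.8, -88.1, as.POSIXct("2016-06-15 14:00:00", tz = "UTC"))
#' @export
sun_azimuth <- function(lat, lon, time_utc) {
  stopifnot(abs(lat) <= 90, lon > -180, lon <= 180)
  t <- as.POSIXct(time_utc, tz = "UTC")
  lt <- as.POSIXlt(t, tz = "UTC")
  hours <- lt$hour + lt$min / 60 + lt$sec / 3600

  # Julian centuries since J2000.0
  jd <- julian_day(lt$year + 1900L, lt$mon + 1L, lt$mday) + (hours - 12) / 24
  jc <- (jd - 2451545) / 36525

  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  seqc <- sin(deg2rad(gmas)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * gmas)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * gmas)) * 0.000289
  stl <- gmls + seqc
  omega <- 125.04 - 1934.136 * jc
  sal <- stl - 0.00569 - 0.00478 * sin(deg2rad(omega))
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos(deg2rad(omega))
  decl <- rad2deg(asin(sin(deg2rad(oc)) * sin(deg2rad(sal))))

  vary <- tan(deg2rad(oc / 2))^2
  eqtime <- 4 * rad2deg(
    vary * sin(2 * deg2rad(gmls)) - 2 * eeo * sin(deg2rad(gmas)) +
      4 * eeo * vary * sin(deg2rad(gmas)) * cos(2 * deg2rad(gmls)) -
      0.5 * vary^2 * sin(4 * deg2rad(gmls)) -
      1.25 * eeo^2 * sin(2 * deg2rad(gmas))
  )
  tst <- (hours * 60 + eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  ha[ha < -180] <- ha[ha < -180] + 360

  zen <- rad2deg(acos(pmin(1, pmax(-1,
    sin(deg2rad(lat)) * sin(deg2rad(decl)) +
      cos(deg2rad(lat)) * cos(deg2rad(decl)) * cos(deg2rad(ha))
  ))))
  el <- 90 - zen
  v <- (sin(deg2rad(lat)) * cos(deg2rad(zen)) - sin(deg2rad(decl))) /
    (cos(deg2rad(lat)) * sin(deg2rad(zen)))
  v <- pmin(1, pmax(-1, v))
  az <- ifelse(ha > 0,
               (rad2deg(acos(v)) + 180) %% 360,
               (540 - rad2deg(acos(v))) %% 360)
  structure(az, elevation_deg = el, below_horizon = el < 0)
}

julian_day <- function(year, month, day) {
  a <- (14 - month) %/% 12
  y <- year + 4800 - a
  m <- month + 12 * a - 3
  day + (153 * m + 2) %/% 5 + 365 * y + y %/% 4 - y %/% 100 + y %/% 400 - 32045
}

#' Great-circle initial bearing between two points
#'
#' The compass bearing at the start of the geodesic from point 1 to point 2,
#' degrees clockwise from north in `[0, 360)`. Thin wrapper around
#' [geosphere::bearing()] with the compass-range convention used throughout
#' the package.
#'
#' @param lat1,lon1 Start point, decimal degrees.
#' @param lat2,lon2 End point, decimal degrees.
#' @return Initial bearing in `[0, 360)`.
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  if (isTRUE(all(lat1 == lat2 & lon1 == lon2))) {
    stop("initial_bearing: start and end points coincide")
  }
  geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2)) %% 360
}

#' Net drift direction and speed from a GPS track
#'
#' The subsurface current advecting the chamber is summarized by the net
#' surface-float displacement over the acquisition window: direction is the
#' great-circle initial bearing from the first to the last fix, speed is the
#' great-circle distance divided by elapsed time (cm/s). Displacements below
#' the GPS noise floor give an unreliable direction, flagged rather than
#' silently reported.
#'
#' @param track Data frame with columns `utc` (POSIXct), `lat`, `lon`,
#'   ordered or orderable by time; >= 2 fixes.
#' @param noise_floor_m Net displacement (m) below which the direction is
#'   flagged unreliable.
#' @return List with `direction_deg`, `speed_cm_s`, `displacement_m`,
#'   `reliable` (logical).
#' @export
drift_direction_and_speed <- function(track, noise_floor_m = 5) {
  stopifnot(all(c("utc", "lat", "lon") %in% names(track)))
  if (nrow(track) < 2) stop("drift_direction_and_speed: need >= 2 GPS fixes")
  track <- track[order(track$utc), ]
  a <- track[1, ]
  b <- track[nrow(track), ]
  dt <- as.numeric(difftime(b$utc, a$utc, units = "secs"))
  if (dt <= 0) stop("drift_direction_and_speed: zero elapsed time")
  dist_m <- geosphere::distGeo(c(a$lon, a$lat), c(b$lon, b$lat))
  reliable <- dist_m >= noise_floor_m
  list(
    direction_deg = if (reliable) initial_bearing(a$lat, a$lon, b$lat, b$lon)
                    else NA_real_,
    speed_cm_s = dist_m * 100 / dt,
    displacement_m = dist_m,
    reliable = reliable
  )
}

#' Deployment context: where, when, and which cues
#'
#' Bundles the metadata needed to compute per-deployment reference
#' directions: start time and position, the surface-float GPS track, the
#' natal-reef transect midpoint, and the wind direction. Wind is stored as
#' the direction the wind blows *toward* (meteorological direction-from
#' inputs must be converted by the reader, i.e. `(from + 180) mod 360`).
#'
#' @param deployment_id Identifier.
#' @param start_utc Deployment start (`POSIXct`, UTC).
#' @param lat,lon Deployment start position, decimal degrees.
#' @param gps_track Data frame `utc, lat, lon` of surface-float fixes.
#' @param natal_reef_lat,natal_reef_lon Transect midpoint.
#' @param wind_toward_deg Wind direction-toward, degrees CW from north.
#' @param age_dph Larval age, days post-hatch.
#' @param acquisition_s Length of the acquisition window, s.
#' @return A `deployment_context` list.
#' @export
deployment_context <- function(deployment_id, start_utc, lat, lon,
                               gps_track = NULL,
                               natal_reef_lat = NA_real_,
                               natal_reef_lon = NA_real_,
                               wind_toward_deg = NA_real_,
                               age_dph = NA_integer_,
                               acquisition_s = 900) {
  stopifnot(abs(lat) <= 90)
  lon <- ((lon + 180) %% 360) - 180
  if (lon == -180) lon <- 180
  structure(
    list(
      deployment_id = as.character(deployment_id)[1],
      start_utc = as.POSIXct(start_utc, tz = "UTC"),
      lat = lat, lon = lon,
      gps_track = gps_track,
      natal_reef_lat = natal_reef_lat, natal_reef_lon = natal_reef_lon,
      wind_toward_deg = if (is.na(wind_toward_deg)) NA_real_ else
        wind_toward_deg %% 360,
      age_dph = as.integer(age_dph),
      acquisition_s = acquisition_s
    ),
    class = "deployment_context"
  )
}

#' Reference directions for one deployment
#'
#' Computes the cue directions against which a larva's mean bearing is
#' tested: sun azimuth at the midpoint of the acquisition window, bearing
#' from the deployment start to the natal-reef transect midpoint, net drift
#' (current) direction from the GPS track, and wind direction-toward.
#' Unavailable or unreliable references are `NA`.
#'
#' @param ctx A [deployment_context()].
#' @param noise_floor_m Passed to [drift_direction_and_speed()].
#' @return List with `sun_azimuth_deg`, `natal_reef_deg`, `current_deg`,
#'   `current_speed_cm_s`, `wind_deg`.
#' @export
reference_directions <- function(ctx, noise_floor_m = 5) {
  stopifnot(inherits(ctx, "deployment_context"))
  mid <- ctx$start_utc + ctx$acquisition_s / 2
  sun <- as.numeric(sun_azimuth(ctx$lat, ctx$lon, mid))
  reef <- if (is.na(ctx$natal_reef_lat)) NA_real_ else
    initial_bearing(ctx$lat, ctx$lon, ctx$natal_reef_lat, ctx$natal_reef_lon)
  cur <- list(direction_deg = NA_real_, speed_cm_s = NA_real_)
  if (!is.null(ctx$gps_track) && nrow(ctx$gps_track) >= 2) {
    cur <- drift_direction_and_speed(ctx$gps_track, noise_floor_m)
  }
  list(
    sun_azimuth_deg = sun,
    natal_reef_deg = reef,
    current_deg = cur$direction_deg,
    current_speed_cm_s = cur$speed_cm_s,
    wind_deg = ctx$wind_toward_deg
  )
}

#' Age-group labels for the ontogenetic bins
#'
#' Bins ages (days post-hatch) into the developmentally meaningful groups
#' pre-flexion (2-10), post-flexion (12-20) and pre-settlement (22-30).
#'
#' @param age_dph Integer ages.
#' @param breaks Named list of inclusive `[lo, hi]` ranges.
#' @return Character vector of group labels (`NA` outside all bins).
#' @export
age_group <- function(age_dph,
                      breaks = list(`2-10` = c(2, 10),
                                    `12-20` = c(12, 20),
                                    `22-30` = c(22, 30))) {
  out <- rep(NA_character_, length(age_dph))
  for (nm in names(breaks)) {
    b <- breaks[[nm]]
    out[age_dph >= b[1] & age_dph <= b[2]] <- nm
  }
  out
}

#' Hypothesis battery: which goal explains the population's bearings?
#'
#' For every orientation hypothesis (cardinal direction, current direction,
#' wind direction, sun azimuth, natal reef) and every age stratum (all ages
#' plus each ontogenetic group), runs a second-order Rayleigh test on the
#' mean bearings of oriented larvae. The cardinal hypothesis uses raw
#' cardinal mean bearings; each cue hypothesis first re-expresses every
#' larva's bearing relative to its own deployment's reference direction, so
#' a population tracking the cue concentrates near 0 degrees. Larvae with an
#' unavailable reference (e.g. unreliable drift) are dropped from that
#' hypothesis only; strata with fewer than 2 larvae are omitted with a
#' message.
#'
#' @param results Data frame of per-larva results with at least
#'   `deployment_id`, `age_dph`, `classification`, `bearing_cardinal_deg`.
#' @param references Data frame keyed by `deployment_id` with columns
#'   `sun_azimuth_deg`, `natal_reef_deg`, `current_deg`, `wind_deg` (as from
#'   [reference_directions()], one row per deployment).
#' @param age_breaks Passed to [age_group()].
#' @return Data frame with one row per hypothesis x stratum:
#'   `hypothesis, age_group, n, mean_bearing_deg, circ_sd_rad, r, p`.
#' @export
hypothesis_battery <- function(results, references,
                               age_breaks = list(`2-10` = c(2, 10),
                                                 `12-20` = c(12, 20),
                                                 `22-30` = c(22, 30))) {
  stopifnot(all(c("deployment_id", "age_dph", "classification",
                  "bearing_cardinal_deg") %in% names(results)))
  oriented <- results[results$classification == "oriented", , drop = FALSE]
  refs <- references[match(oriented$deployment_id, references$deployment_id), ,
                     drop = FALSE]
  ref_cols <- c(cardinal = NA, current = "current_deg", wind = "wind_deg",
                sun_azimuth = "sun_azimuth_deg", natal_reef = "natal_reef_deg")
  groups <- age_group(oriented$age_dph, breaks = age_breaks)
  strata <- c(list(`all` = rep(TRUE, nrow(oriented))),
              lapply(names(age_breaks), function(g) groups == g))
  names(strata) <- c("all", names(age_breaks))

  rows <- list()
  for (hyp in names(ref_cols)) {
    if (hyp == "cardinal") {
      bearing <- oriented$bearing_cardinal_deg
      ok <- !is.na(bearing)
    } else {
      ref <- refs[[ref_cols[[hyp]]]]
      ok <- !is.na(ref) & !is.na(oriented$bearing_cardinal_deg)
      bearing <- rep(NA_real_, nrow(oriented))
      if (any(ok)) {
        bearing[ok] <- relative_bearings(oriented$bearing_cardinal_deg[ok],
                                         ref[ok])$angles_deg
      }
    }
    for (g in names(strata)) {
      sel <- strata[[g]] & ok
      sel[is.na(sel)] <- FALSE
      if (sum(sel) < 2) {
        message(sprintf(
          "hypothesis_battery: '%s' x '%s' omitted (n = %d < 2)",
          hyp, g, sum(sel)
        ))
        next
      }
      s <- second_order_rayleigh(bearing[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        hypothesis = hyp, age_group = g, n = s$n,
        mean_bearing_deg = s$mean_bearing_deg,
        circ_sd_rad = s$circ_sd_rad, r = s$r, p = s$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Read deployment metadata from CSV
#'
#' Expects columns `deployment_id, start_utc, lat, lon, wind_dir_deg,
#' age_dph`, with `wind_dir_deg` already converted to direction-toward.
#'
#' @param path CSV file path.
#' @return Data frame with `start_utc` parsed as UTC `POSIXct`.
#' @export
read_metadata_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("deployment_id", "start_utc", "lat", "lon", "wind_dir_deg",
            "age_dph")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("read_metadata_csv: '%s' lacks column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  d$start_utc <- as.POSIXct(d$start_utc, tz = "UTC")
  d
}

#' Read GPS fixes from CSV
#'
#' Expects columns `deployment_id, utc, lat, lon`.
#'
#' @param path CSV file path.
#' @return Named list of per-deployment data frames ordered by time.
#' @export
read_gps_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("deployment_id", "utc", "lat", "lon")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("read_gps_csv: '%s' lacks column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  d$utc <- as.POSIXct(d$utc, tz = "UTC")
  out <- lapply(split(d, d$deployment_id), function(g) g[order(g$utc), ])
  out[order(names(out))]
}
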