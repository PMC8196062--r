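#' Configuration of a synthetic DISC cohort
#'
#' Defines the generative model for a cohort of drifting-chamber
#' deployments: one larva per deployment performing a biased correlated
#' random walk (BCRW) in a rotating 20 cm arena, plus the chamber compass,
#' surface-float GPS drift, and environmental metadata. The strategy field
#' selects among alternative orientation-goal hypotheses:
#'
#' * `H0_none` — no directional goal (`kappa_goal` forced to 0);
#' * `H1_single_bearing` — all larvae share one constant compass bearing;
#' * `H2_condition_dependent` — the goal flips between two bearings at a
#'   switch age (east early / west late by default);
#' * `H3_context_dependent` — each larva aims at the nearest point of the
#'   configured reef line from its deployment position;
#' * `H4_mixed` — each larva draws its goal from a mixture of bearings.
#'
#' A fraction of larvae can carry an *arena-fixed* goal (a camera-frame
#' bearing that rotates with the chamber): these emulate attraction to a
#' chamber feature, the artifact the device-bias filter must catch, as
#' opposed to cardinal-fixed goals which represent genuine orientation.
#'
#' Per step the swimming heading is drawn von Mises around the circular
#' blend of the previous heading (weight `persistence_weight`) and the goal
#' direction (weight `1 - persistence_weight`) with concentration
#' `kappa_goal`, plus a wrapped-normal turning jitter whose SD declines with
#' age (`turning_sd_model`, degrees: `intercept + slope * age`). Step length
#' is `speed(age) * dt` with truncated-normal noise, where
#' `speed(age) = intercept + slope * age` (cm/s). The wall is reflecting
#' (radial reflection). Defaults anchor the speed model at 0.45 cm/s at
#' 2 dph and 0.62 cm/s at 30 dph.
#'
#' @param n_larvae Number of deployments.
#' @param ages_dph Ages assigned to larvae 1..n (recycled); default 2-30 by
#'   2, 8 larvae per age.
#' @param strategy Orientation-strategy hypothesis, see Details.
#' @param goal_bearings_deg Strategy goal bearing(s), degrees CW from north.
#' @param mixture_weights `H4_mixed` mixture weights over
#'   `goal_bearings_deg`.
#' @param switch_age_dph `H2_condition_dependent` switch age.
#' @param arena_fixed_fraction Fraction of larvae whose goal is arena-fixed.
#' @param kappa_goal von Mises concentration of the heading around the
#'   blended target direction.
#' @param persistence_weight Weight of the previous heading in the blend,
#'   `[0, 1]`.
#' @param speed_model List `intercept`, `slope` (cm/s per dph), `noise_sd`
#'   (cm/s).
#' @param turning_sd_model List `intercept`, `slope` (degrees per dph);
#'   floored at 5 degrees.
#' @param rotation Chamber rotation profile: `list(type = "constant",
#'   rate_deg_s = )` or `list(type = "random_walk", sd_deg = )`.
#' @param trial_s,dt_s Acquisition length and time step, s (`dt_s` must
#'   divide `trial_s`).
#' @param arena_radius_cm Arena radius, cm.
#' @param start_radius_frac Larvae start uniformly within this fraction of
#'   the arena radius.
#' @param site List with `natal_reef` (lat, lon), `reef_line` (two lat/lon
#'   endpoints of the transect), `offshore_bearing_deg` and
#'   `offshore_distance_m` of deployment starts relative to the reef, and
#'   `utc_offset_h` of local time.
#' @param current List `mean_dir_deg`, `kappa`, `mean_speed_cm_s`,
#'   `speed_sd`: per-deployment drift drawn von Mises / truncated normal.
#' @param wind List `mean_toward_deg`, `kappa`: per-deployment wind
#'   direction-toward.
#' @param gps List `fix_interval_s`, `jitter_m`.
#' @param seed Integer seed; every cohort quantity is a deterministic
#'   function of it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_larvae = 120,
                       ages_dph = rep(seq(2, 30, by = 2), each = 8),
                       strategy = c("H4_mixed", "H0_none",
                                    "H1_single_bearing",
                                    "H2_condition_dependent",
                                    "H3_context_dependent"),
                       goal_bearings_deg = c(90, 270),
                       mixture_weights = c(0.5, 0.5),
                       switch_age_dph = 12,
                       arena_fixed_fraction = 0,
                       kappa_goal = 2,
                       persistence_weight = 0.5,
                       speed_model = list(intercept = 0.45 - 2 * 0.17 / 28,
                                          slope = 0.17 / 28,
                                          noise_sd = 0.1),
                       turning_sd_model = list(intercept = 52, slope = -0.7),
                       rotation = list(type = "constant", rate_deg_s = 0.5),
                       trial_s = 900, dt_s = 1,
                       arena_radius_cm = 10,
                       start_radius_frac = 0.8,
                       site = list(
                         natal_reef = c(lat = 16.804, lon = -88.086),
                         reef_line = rbind(c(16.801, -88.086),
                                           c(16.807, -88.086)),
                         offshore_bearing_deg = 90,
                         offshore_distance_m = 500,
                         utc_offset_h = -6
                       ),
                       current = list(mean_dir_deg = 200, kappa = 4,
                                      mean_speed_cm_s = 4.38,
                                      speed_sd = 2.72),
                       wind = list(mean_toward_deg = 270, kappa = 4),
                       gps = list(fix_interval_s = 60, jitter_m = 2),
                       seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(
    n_larvae >= 1,
    kappa_goal >= 0,
    persistence_weight >= 0, persistence_weight <= 1,
    arena_fixed_fraction >= 0, arena_fixed_fraction <= 1,
    trial_s %% dt_s == 0,
    length(goal_bearings_deg) >= 1,
    arena_radius_cm > 0,
    start_radius_frac > 0, start_radius_frac <= 1
  )
  if (strategy == "H4_mixed") {
    stopifnot(length(mixture_weights) == length(goal_bearings_deg),
              all(mixture_weights >= 0), sum(mixture_weights) > 0)
  }
  if (strategy == "H2_condition_dependent" &&
      length(goal_bearings_deg) < 2) {
    stop("sim_config: H2_condition_dependent needs two goal bearings (early, late)")
  }
  structure(
    list(
      n_larvae = as.integer(n_larvae),
      ages_dph = rep_len(as.integer(ages_dph), n_larvae),
      strategy = strategy,
      goal_bearings_deg = goal_bearings_deg %% 360,
      mixture_weights = mixture_weights / sum(mixture_weights),
      switch_age_dph = switch_age_dph,
      arena_fixed_fraction = arena_fixed_fraction,
      kappa_goal = kappa_goal,
      persistence_weight = persistence_weight,
      speed_model = speed_model,
      turning_sd_model = turning_sd_model,
      rotation = rotation,
      trial_s = trial_s, dt_s = dt_s,
      arena_radius_cm = arena_radius_cm,
      start_radius_frac = start_radius_frac,
      site = site, current = current, wind = wind, gps = gps,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# von Mises deviates around 0 (radians), Best & Fisher (1979) rejection.
# kappa ~ 0 degenerates to the uniform, very large kappa to a point mass.
rvm_rad <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-6) return(stats::runif(n, -pi, pi))
  if (kappa > 1e7) return(rep(0, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.6))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok]))))
  }
  out[seq_len(n)]
}

# nearest point on the reef segment (rows lat/lon) to p = c(lat, lon),
# in a local planar approximation adequate at <1 km scales
nearest_reef_point <- function(reef_line, lat, lon) {
  to_xy <- function(la, lo) {
    c((lo - lon) * 111320 * cos(deg2rad(lat)), (la - lat) * 111320)
  }
  a <- to_xy(reef_line[1, 1], reef_line[1, 2])
  b <- to_xy(reef_line[2, 1], reef_line[2, 2])
  ab <- b - a
  tt <- sum((c(0, 0) - a) * ab) / sum(ab^2)
  tt <- min(1, max(0, tt))
  q <- a + tt * ab
  c(lat = lat + q[2] / 111320,
    lon = lon + q[1] / (111320 * cos(deg2rad(lat))))
}

speed_at_age <- function(speed_model, age) {
  max(0, speed_model$intercept + speed_model$slope * age)
}

turning_sd_at_age <- function(turning_sd_model, age) {
  max(5, turning_sd_model$intercept + turning_sd_model$slope * age)
}

#' Simulate one DISC deployment
#'
#' Generates a single larva's biased correlated random walk in the rotating
#' arena together with the chamber compass record, the surface-float GPS
#' drift, the deployment metadata, and the generative ground truth. The
#' result is fully determined by `config$seed` and `larva_index`.
#'
#' The walk runs in the cardinal frame (the physical frame larvae swim in);
#' recorded positions are converted to the camera frame via the chamber
#' heading, exactly inverting the correction applied by
#' [rotate_to_cardinal()]. Arena-fixed goals are converted to a cardinal
#' target through the instantaneous chamber heading, so they co-rotate with
#' the chamber.
#'
#' @param config A [sim_config()].
#' @param larva_index Index in `1:config$n_larvae`.
#' @return A `simulated_deployment`: list with `trajectory`
#'   ([trajectory()], camera frame), `compass` ([compass_series()]),
#'   `context` ([deployment_context()]), and `truth` (list of generative
#'   parameters: strategy, goal bearing and frame, kappa, persistence, age,
#'   swim speed, current, wind).
#' @export
simulate_trajectory <- function(config, larva_index) {
  stopifnot(inherits(config, "sim_config"),
            larva_index >= 1, larva_index <= config$n_larvae)
  seed_i <- (abs(config$seed) + 104729 * as.integer(larva_index)) %%
    .Machine$integer.max
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed_i)

  age <- config$ages_dph[larva_index]
  id <- sprintf("d%03d", larva_index)
  site <- config$site

  ## deployment context -----------------------------------------------------
  day <- sample(0:122, 1)  # within a ~4-month field season
  window <- sample(c("am", "pm"), 1)
  local_h <- if (window == "am") stats::runif(1, 7, 11.75) else
    stats::runif(1, 14, 17.75)
  start_utc <- as.POSIXct("2016-05-01 00:00:00", tz = "UTC") +
    day * 86400 + (local_h - site$utc_offset_h) * 3600
  start <- geosphere::destPoint(
    c(site$natal_reef["lon"], site$natal_reef["lat"]),
    site$offshore_bearing_deg,
    site$offshore_distance_m + stats::rnorm(1, 0, 50)
  )
  start <- geosphere::destPoint(start, stats::runif(1, 0, 360),
                                abs(stats::rnorm(1, 0, 150)))
  start_lat <- start[2]; start_lon <- start[1]

  current_dir <- (config$current$mean_dir_deg +
                    rad2deg(rvm_rad(1, config$current$kappa))) %% 360
  current_speed <- max(0.5, stats::rnorm(1, config$current$mean_speed_cm_s,
                                         config$current$speed_sd))
  wind_toward <- (config$wind$mean_toward_deg +
                    rad2deg(rvm_rad(1, config$wind$kappa))) %% 360

  ## orientation goal -------------------------------------------------------
  goal <- switch(config$strategy,
    H0_none = 0,
    H1_single_bearing = config$goal_bearings_deg[1],
    H2_condition_dependent =
      if (age < config$switch_age_dph) config$goal_bearings_deg[1]
      else config$goal_bearings_deg[2],
    H3_context_dependent = {
      q <- nearest_reef_point(site$reef_line, start_lat, start_lon)
      initial_bearing(start_lat, start_lon, q["lat"], q["lon"])
    },
    H4_mixed = sample(config$goal_bearings_deg, 1,
                      prob = config$mixture_weights)
  )
  goal <- as.numeric(goal)
  goal_frame <- if (stats::runif(1) < config$arena_fixed_fraction)
    "arena" else "cardinal"
  kappa <- if (config$strategy == "H0_none") 0 else config$kappa_goal

  ## chamber heading --------------------------------------------------------
  nt <- config$trial_s / config$dt_s          # recorded positions
  t_s <- seq(0, by = config$dt_s, length.out = nt)
  h0 <- stats::runif(1, 0, 360)
  heading_chamber <- switch(config$rotation$type,
    constant = h0 + config$rotation$rate_deg_s * t_s,
    random_walk = h0 + cumsum(c(0, stats::rnorm(nt - 1, 0,
      config$rotation$sd_deg * config$dt_s))),
    stop("sim_config: unknown rotation profile type")
  )

  ## biased correlated random walk (cardinal frame) -------------------------
  n_steps <- nt - 1L
  w <- config$persistence_weight
  vm_noise <- rvm_rad(n_steps, kappa)
  turn_jitter <- stats::rnorm(n_steps, 0,
                              deg2rad(turning_sd_at_age(config$turning_sd_model,
                                                        age)))
  step_len <- pmax(0, stats::rnorm(n_steps,
                                   speed_at_age(config$speed_model, age),
                                   config$speed_model$noise_sd)) * config$dt_s
  goal_rad <- if (goal_frame == "arena") {
    deg2rad((goal + heading_chamber[-nt]) %% 360)  # co-rotates with chamber
  } else {
    rep(deg2rad(goal), n_steps)
  }
  sin_g <- sin(goal_rad); cos_g <- cos(goal_rad)

  R <- config$arena_radius_cm
  u <- stats::runif(2)
  r0 <- R * config$start_radius_frac * sqrt(u[1])
  th0 <- 2 * pi * u[2]
  x <- r0 * sin(th0); y <- r0 * cos(th0)
  X <- numeric(nt); Y <- numeric(nt)
  X[1] <- x; Y[1] <- y
  prev <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n_steps)) {
    blend <- atan2(w * sin(prev) + (1 - w) * sin_g[i],
                   w * cos(prev) + (1 - w) * cos_g[i])
    h <- blend + vm_noise[i] + turn_jitter[i]
    x <- x + step_len[i] * sin(h)
    y <- y + step_len[i] * cos(h)
    rr <- sqrt(x^2 + y^2)
    if (rr > R) {              # radial reflection at the wall
      fac <- (2 * R - rr) / rr
      x <- x * fac
      y <- y * fac
    }
    prev <- h
    X[i + 1] <- x; Y[i + 1] <- y
  }

  ## camera-frame positions: cardinal bearing - chamber heading -------------
  beta_card <- atan2(X, Y)
  rad_pos <- sqrt(X^2 + Y^2)
  beta_cam <- beta_card - deg2rad(heading_chamber)
  traj <- trajectory(id, t_s, rad_pos * sin(beta_cam), rad_pos * cos(beta_cam),
                     arena_radius_cm = R, acclimation_s = 0)

  ## GPS drift of the surface float -----------------------------------------
  fix_t <- seq(0, config$trial_s, by = config$gps$fix_interval_s)
  drift_m <- current_speed / 100 * fix_t
  fixes <- geosphere::destPoint(c(start_lon, start_lat), current_dir, drift_m)
  jit <- matrix(stats::rnorm(2 * length(fix_t), 0, config$gps$jitter_m),
                ncol = 2)
  gps_track <- data.frame(
    utc = start_utc + fix_t,
    lat = fixes[, 2] + jit[, 2] / 111320,
    lon = fixes[, 1] + jit[, 1] / (111320 * cos(deg2rad(start_lat)))
  )

  ctx <- deployment_context(
    id, start_utc, start_lat, start_lon,
    gps_track = gps_track,
    natal_reef_lat = site$natal_reef["lat"],
    natal_reef_lon = site$natal_reef["lon"],
    wind_toward_deg = wind_toward,
    age_dph = age,
    acquisition_s = config$trial_s
  )

  structure(
    list(
      trajectory = traj,
      compass = compass_series(t_s, heading_chamber %% 360),
      context = ctx,
      truth = list(
        deployment_id = id, age_dph = age,
        strategy = config$strategy,
        goal_bearing_deg = goal %% 360, goal_frame = goal_frame,
        kappa_goal = kappa, persistence_weight = w,
        swim_speed_cm_s = speed_at_age(config$speed_model, age),
        turning_sd_deg = turning_sd_at_age(config$turning_sd_model, age),
        current_dir_deg = current_dir, current_speed_cm_s = current_speed,
        wind_toward_deg = wind_toward,
        seed = seed_i
      )
    ),
    class = "simulated_deployment"
  )
}

#' Simulate a full DISC cohort
#'
#' Generates `config$n_larvae` deployments (see [simulate_trajectory()])
#' plus a ground-truth table. Deterministic under `config$seed`: each
#' deployment derives its own sub-seed from the cohort seed and its index.
#'
#' @param config A [sim_config()].
#' @return A `disc_cohort`: list with `deployments` (list of
#'   `simulated_deployment`), `truth` (data frame, one row per deployment),
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  deployments <- lapply(seq_len(config$n_larvae),
                        function(i) simulate_trajectory(config, i))
  truth <- do.call(rbind, lapply(deployments, function(d) {
    as.data.frame(d$truth[c("deployment_id", "age_dph", "strategy",
                            "goal_bearing_deg", "goal_frame", "kappa_goal",
                            "persistence_weight", "swim_speed_cm_s",
                            "turning_sd_deg", "current_dir_deg",
                            "current_speed_cm_s", "wind_toward_deg")],
                  stringsAsFactors = FALSE)
  }))
  structure(list(deployments = deployments, truth = truth, config = config),
            class = "disc_cohort")
}

#' @export
print.disc_cohort <- function(x, ...) {
  cat(sprintf(
    "<disc_cohort> %d deployments, strategy %s, ages %d-%d dph, seed %d\n",
    length(x$deployments), x$config$strategy,
    min(x$config$ages_dph), max(x$config$ages_dph), x$config$seed
  ))
  invisible(x)
}

#' Write a simulated cohort as a runnable data directory
#'
#' Emits the CSV dialects consumed by the analysis pipeline
#' (`trajectories.csv`, `compass.csv`, `metadata.csv`, `gps.csv`), the
#' ground truth (`truth.csv`), and the site/analysis constants
#' (`config.yml`), so one call produces a complete directory for
#' [run_pipeline()].
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "disc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dep <- cohort$deployments

  traj <- do.call(rbind, lapply(dep, function(d) {
    data.frame(deployment_id = d$trajectory$deployment_id,
               t_s = d$trajectory$t_s,
               x_cm = round(d$trajectory$x_cm, 4),
               y_cm = round(d$trajectory$y_cm, 4))
  }))
  utils::write.csv(traj, file.path(dir, "trajectories.csv"),
                   row.names = FALSE, quote = FALSE)

  comp <- do.call(rbind, lapply(dep, function(d) {
    data.frame(deployment_id = d$trajectory$deployment_id,
               t_s = d$compass$t_s,
               heading_deg = round(d$compass$heading_deg, 3))
  }))
  utils::write.csv(comp, file.path(dir, "compass.csv"),
                   row.names = FALSE, quote = FALSE)

  meta <- do.call(rbind, lapply(dep, function(d) {
    data.frame(deployment_id = d$context$deployment_id,
               start_utc = format(d$context$start_utc,
                                  "%Y-%m-%d %H:%M:%S"),
               lat = round(d$context$lat, 6),
               lon = round(d$context$lon, 6),
               wind_dir_deg = round(d$context$wind_toward_deg, 2),
               age_dph = d$context$age_dph)
  }))
  utils::write.csv(meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)

  gps <- do.call(rbind, lapply(dep, function(d) {
    g <- d$context$gps_track
    data.frame(deployment_id = d$context$deployment_id,
               utc = format(g$utc, "%Y-%m-%d %H:%M:%S"),
               lat = round(g$lat, 7), lon = round(g$lon, 7))
  }))
  utils::write.csv(gps, file.path(dir, "gps.csv"),
                   row.names = FALSE, quote = FALSE)

  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)

  site <- cohort$config$site
  yaml::write_yaml(list(
    alpha = 0.05,
    rotation_sign = 1,
    natal_reef_lat = as.numeric(site$natal_reef["lat"]),
    natal_reef_lon = as.numeric(site$natal_reef["lon"]),
    gps_noise_floor_m = 5,
    acclimation_s = 0,
    arena_radius_cm = cohort$config$arena_radius_cm,
    age_groups = list(`2-10` = c(2, 10), `12-20` = c(12, 20),
                      `22-30` = c(22, 30))
  ), file.path(dir, "config.yml"))
  invisible(dir)
}
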