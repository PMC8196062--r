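#' Default analysis configuration
#'
#' Site and screening constants used by [run_pipeline()] /
#' [analyze_deployments()]: the uniformity-screen level `alpha`, the
#' camera-to-cardinal `rotation_sign` convention, the natal-reef transect
#' midpoint, the GPS noise floor for drift directions, the acclimation trim,
#' the arena radius, and the ontogenetic age bins.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of configuration values.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    alpha = 0.05,
    rotation_sign = 1,
    natal_reef_lat = 16.804,
    natal_reef_lon = -88.086,
    gps_noise_floor_m = 5,
    acclimation_s = 300,
    arena_radius_cm = 10,
    center_cutoff_cm = 0.5,
    age_groups = list(`2-10` = c(2, 10), `12-20` = c(12, 20),
                      `22-30` = c(22, 30))
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read an analysis configuration file
#'
#' Plain-text key-value (YAML) file with any subset of the
#' [analysis_config()] keys; unspecified keys keep their defaults.
#'
#' @param path Config file path.
#' @return Named list of configuration values.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$age_groups)) {
    vals$age_groups <- lapply(vals$age_groups, as.numeric)
  }
  do.call(analysis_config, vals)
}

#' Analyze a set of deployments
#'
#' Core orchestration: for every deployment with both a trajectory and a
#' compass record, subsamples to 1 Hz, computes kinematics, classifies the
#' deployment (non-oriented / device-biased / oriented), computes the
#' per-deployment reference directions, then runs the second-order
#' hypothesis battery on oriented larvae and the ontogenetic trend fits.
#' Deployments lacking a compass record are skipped with a message.
#'
#' @param trajectories Named list of [trajectory()] objects (raw rate).
#' @param compasses Named list of [compass_series()] keyed by deployment id.
#' @param metadata Data frame as from [read_metadata_csv()] (wind already
#'   direction-toward).
#' @param gps Named list of GPS data frames keyed by deployment id (may be
#'   `NULL`).
#' @param config An [analysis_config()].
#' @return A `run_report`: list with `counts` (total / non_oriented /
#'   device_biased / oriented), `per_larva` (data frame), `references`
#'   (data frame), `group_summaries` (hypothesis battery grid),
#'   `trend_speed`, `trend_turning`, `trend_logistic`, `provenance`.
#' @export
analyze_deployments <- function(trajectories, compasses, metadata,
                                gps = NULL, config = analysis_config()) {
  rows <- list()
  refs <- list()
  for (id in names(trajectories)) {
    if (is.null(compasses[[id]])) {
      message(sprintf("analyze_deployments: '%s' skipped (no compass record)", id))
      next
    }
    traj <- trajectories[[id]]
    fa <- classify_deployment(traj, compasses[[id]],
                              alpha = config$alpha,
                              rotation_sign = config$rotation_sign,
                              center_cutoff_cm = config$center_cutoff_cm)
    kin <- kinematics_summary(subsample_1hz(traj))
    meta <- metadata[metadata$deployment_id == id, , drop = FALSE]
    age <- if (nrow(meta)) meta$age_dph[1] else NA_integer_
    rows[[id]] <- data.frame(
      deployment_id = id,
      age_dph = age,
      mean_speed_cm_s = kin$mean_speed_cm_s,
      mean_turning_deg = kin$mean_turning_deg,
      n = fa$n,
      rho_camera = fa$rho_camera,
      rho_cardinal = fa$rho_cardinal,
      bearing_cardinal_deg = fa$bearing_cardinal_deg,
      p_cardinal = fa$p_cardinal,
      classification = fa$classification,
      stringsAsFactors = FALSE
    )
    if (nrow(meta)) {
      ctx <- deployment_context(
        id, meta$start_utc[1], meta$lat[1], meta$lon[1],
        gps_track = gps[[id]],
        natal_reef_lat = config$natal_reef_lat,
        natal_reef_lon = config$natal_reef_lon,
        wind_toward_deg = meta$wind_dir_deg[1],
        age_dph = age
      )
      rd <- reference_directions(ctx, noise_floor_m = config$gps_noise_floor_m)
      refs[[id]] <- data.frame(
        deployment_id = id,
        sun_azimuth_deg = rd$sun_azimuth_deg,
        natal_reef_deg = rd$natal_reef_deg,
        current_deg = rd$current_deg,
        current_speed_cm_s = rd$current_speed_cm_s,
        wind_deg = rd$wind_deg,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("analyze_deployments: no analyzable deployment")
  per_larva <- do.call(rbind, rows)
  rownames(per_larva) <- NULL
  references <- if (length(refs)) do.call(rbind, refs) else
    data.frame(deployment_id = character(0))
  rownames(references) <- NULL

  counts <- list(
    total = nrow(per_larva),
    non_oriented = sum(per_larva$classification == "non_oriented"),
    device_biased = sum(per_larva$classification == "device_biased"),
    oriented = sum(per_larva$classification == "oriented")
  )

  group_summaries <- if (counts$oriented >= 2 && nrow(references)) {
    suppressMessages(hypothesis_battery(per_larva, references,
                                        age_breaks = config$age_groups))
  } else NULL

  usable <- !is.na(per_larva$age_dph)
  trend_speed <- if (sum(usable) >= 3 &&
                     length(unique(per_larva$age_dph[usable])) >= 2)
    fit_linear_trend(per_larva[usable, ], "speed") else NULL
  trend_turning <- if (sum(usable) >= 3 &&
                       length(unique(per_larva$age_dph[usable])) >= 2)
    fit_linear_trend(per_larva[usable, ], "turning") else NULL
  trend_logistic <- if (sum(usable) >= 3)
    suppressWarnings(fit_orientation_logistic(per_larva[usable, ])) else NULL

  structure(
    list(
      counts = counts,
      per_larva = per_larva,
      references = references,
      group_summaries = group_summaries,
      trend_speed = trend_speed,
      trend_turning = trend_turning,
      trend_logistic = trend_logistic,
      provenance = list(
        config = config,
        config_hash = config_hash(config),
        package_version = as.character(utils::packageVersion("discorient")),
        r_version = R.version.string
      )
    ),
    class = "run_report"
  )
}

# FNV-style rolling hash over the deparsed configuration; provenance only
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 216613626L
  for (b in bytes) {
    h <- bitwXor(h, as.integer(b))
    h <- as.integer((as.double(h) * 16777619) %% 2147483647)
  }
  sprintf("%08x", h)
}

#' Analyze a simulated cohort in memory
#'
#' Runs [analyze_deployments()] directly on a [simulate_cohort()] result
#' without a file round-trip; the classification and battery are identical
#' to analyzing the written CSVs.
#'
#' @param cohort A `disc_cohort`.
#' @param config An [analysis_config()]; its acclimation default is
#'   overridden to 0 s because simulated trajectories contain only the
#'   acquisition window.
#' @return A `run_report` (see [analyze_deployments()]).
#' @export
analyze_cohort <- function(cohort, config = analysis_config(acclimation_s = 0)) {
  stopifnot(inherits(cohort, "disc_cohort"))
  dep <- cohort$deployments
  ids <- vapply(dep, function(d) d$trajectory$deployment_id, character(1))
  trajectories <- stats::setNames(lapply(dep, function(d) d$trajectory), ids)
  compasses <- stats::setNames(lapply(dep, function(d) d$compass), ids)
  metadata <- do.call(rbind, lapply(dep, function(d) {
    data.frame(deployment_id = d$context$deployment_id,
               start_utc = d$context$start_utc,
               lat = d$context$lat, lon = d$context$lon,
               wind_dir_deg = d$context$wind_toward_deg,
               age_dph = d$context$age_dph,
               stringsAsFactors = FALSE)
  }))
  gps <- stats::setNames(lapply(dep, function(d) d$context$gps_track), ids)
  analyze_deployments(trajectories, compasses, metadata, gps, config)
}

#' Run the full analysis pipeline on a data directory
#'
#' Reads `trajectories.csv`, `compass.csv`, `metadata.csv`, and (if present)
#' `gps.csv` plus `config.yml` from `data_dir`, runs
#' [analyze_deployments()], and optionally writes the per-larva table, the
#' group-summary grid, the fitted trend curves and a machine-readable run
#' summary to `out_dir`. Deterministic given its inputs: all randomness in
#' the package lives in the simulator.
#'
#' @param data_dir Directory of input CSVs.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param config An [analysis_config()]; defaults to `config.yml` in
#'   `data_dir` when present.
#' @return A `run_report`, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(data_dir, out_dir = NULL, config = NULL) {
  if (is.null(config)) {
    cfg_path <- file.path(data_dir, "config.yml")
    config <- if (file.exists(cfg_path)) read_analysis_config(cfg_path)
      else analysis_config()
  }
  trajectories <- read_trajectories_csv(
    file.path(data_dir, "trajectories.csv"),
    arena_radius_cm = config$arena_radius_cm,
    acclimation_s = config$acclimation_s
  )
  compasses <- read_compass_csv(file.path(data_dir, "compass.csv"))
  metadata <- read_metadata_csv(file.path(data_dir, "metadata.csv"))
  gps_path <- file.path(data_dir, "gps.csv")
  gps <- if (file.exists(gps_path)) read_gps_csv(gps_path) else NULL

  report <- analyze_deployments(trajectories, compasses, metadata, gps, config)
  if (!is.null(out_dir)) {
    write_run_report(report, out_dir)
    return(invisible(report))
  }
  report
}

#' Write a run report to disk
#'
#' Emits `per_larva.csv` (full precision), `group_summary.csv`,
#' `trends.csv` (age grid with point prediction and 95% band for each
#' linear trend), and `run_summary.json` (counts, trend tests, provenance).
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_larva, file.path(out_dir, "per_larva.csv"),
                   row.names = FALSE)
  if (!is.null(report$group_summaries)) {
    utils::write.csv(report$group_summaries,
                     file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
  }
  curves <- list()
  for (nm in c("trend_speed", "trend_turning")) {
    f <- report[[nm]]
    if (!is.null(f)) {
      cv <- trend_curve(f)
      cv$response <- f$response
      curves[[nm]] <- cv
    }
  }
  if (length(curves)) {
    utils::write.csv(do.call(rbind, curves), file.path(out_dir, "trends.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    counts = report$counts,
    oriented_fraction = report$counts$oriented / report$counts$total,
    trends = lapply(
      Filter(Negate(is.null),
             report[c("trend_speed", "trend_turning", "trend_logistic")]),
      function(f) f[c("response", "slope", "intercept", "test_stat", "df", "p")]
    ),
    provenance = report$provenance[c("config_hash", "package_version",
                                     "r_version")]
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Format the oriented fraction for reporting
#'
#' @param n_oriented,n_total Counts of oriented and total deployments.
#' @return A string such as `"77.5% (93 of 120)"`.
#' @examples
#' format_oriented_fraction(93, 120)
#' @export
format_oriented_fraction <- function(n_oriented, n_total) {
  stopifnot(n_total > 0, n_oriented >= 0, n_oriented <= n_total)
  sprintf("%.1f%% (%d of %d)", 100 * n_oriented / n_total, n_oriented, n_total)
}

#' Format the hypothesis-battery grid as a readable table
#'
#' Human-readable rendering of the group summaries: mean bearings in
#' degrees with 1 decimal, circular SD (radians), r and p with 2 decimals —
#' machine outputs keep full precision.
#'
#' @param group_summaries Data frame from [hypothesis_battery()].
#' @return Character vector of formatted lines, invisibly; also printed.
#' @export
format_group_table <- function(group_summaries) {
  stopifnot(is.data.frame(group_summaries))
  lines <- c(sprintf("%-12s %-6s %4s  %-14s %5s %6s",
                     "hypothesis", "ages", "n", "mean +/- SD", "r", "p"))
  for (i in seq_len(nrow(group_summaries))) {
    g <- group_summaries[i, ]
    lines <- c(lines, sprintf(
      "%-12s %-6s %4d  %6.1f +/- %-5.2f %5.2f %6.2f%s",
      g$hypothesis, g$age_group, g$n, g$mean_bearing_deg, g$circ_sd_rad,
      g$r, g$p, if (g$p < 0.05) " *" else ""
    ))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> %d deployments: %s oriented, %d device-biased, %d non-oriented\n",
    x$counts$total,
    format_oriented_fraction(x$counts$oriented, x$counts$total),
    x$counts$device_biased, x$counts$non_oriented
  ))
  invisible(x)
}
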