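test_that("cohorts are bit-identical under a seed and differ across seeds", {
  cfg <- sim_config(n_larvae = 3, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(sim_config(n_larvae = 3, seed = 42))
  expect_identical(a$truth, b$truth)
  expect_identical(a$deployments[[2]]$trajectory$x_cm,
                   b$deployments[[2]]$trajectory$x_cm)
  cc <- simulate_cohort(sim_config(n_larvae = 3, seed = 43))
  expect_false(identical(a$deployments[[1]]$trajectory$x_cm,
                         cc$deployments[[1]]$trajectory$x_cm))
})

test_that("default cohort structure: 120 deployments, 8 per age, 2-30 dph", {
  cfg <- sim_config(seed = 1)
  expect_length(cfg$ages_dph, 120)
  expect_true(all(table(cfg$ages_dph) == 8))
  expect_equal(sort(unique(cfg$ages_dph)), seq(2, 30, 2))
})

test_that("trajectories stay inside the arena and contain no NaN", {
  for (strategy in c("H0_none", "H1_single_bearing", "H3_context_dependent")) {
    cfg <- sim_config(n_larvae = 2, strategy = strategy, seed = 99)
    coh <- simulate_cohort(cfg)
    for (d in coh$deployments) {
      tr <- d$trajectory
      expect_false(any(is.na(c(tr$x_cm, tr$y_cm, tr$t_s))))
      expect_true(all(sqrt(tr$x_cm^2 + tr$y_cm^2) <= cfg$arena_radius_cm + 1e-9))
      expect_false(any(is.na(d$compass$heading_deg)))
      expect_false(any(is.na(d$context$gps_track$lat)))
    }
  }
})

test_that("goalless cohorts carry no population-level direction", {
  # Under H0 a slow confined walk still clusters its positions (they are
  # autocorrelated at 1 Hz), so per-larva Rayleigh tests over-reject; what
  # H0 guarantees is that the per-larva mean bearings are uniform across
  # larvae, leaving the second-order test quiet and the bearings spread
  # around the whole compass rose.
  n_rep <- 150
  bearings <- vapply(1:n_rep, function(k) {
    cfg <- sim_config(n_larvae = 1, strategy = "H0_none", seed = 20000 + k)
    d <- simulate_trajectory(cfg, 1)
    classify_deployment(d$trajectory, d$compass)$bearing_cardinal_deg
  }, numeric(1))
  bearings <- bearings[!is.na(bearings)]
  s <- second_order_rayleigh(bearings)
  expect_gt(s$p_value, 0.05)
  expect_lt(s$r, 0.15)
  quadrant <- table(cut(bearings, c(0, 90, 180, 270, 360)))
  expect_true(all(quadrant > 0.1 * length(bearings)))
})

test_that("strong concentration drives the mean cardinal bearing to the goal", {
  # concentration limit: heading noise off (large kappa, no persistence,
  # turning jitter at its floor) pins the larva to the wall at the goal
  errs <- vapply(1:10, function(k) {
    cfg <- sim_config(n_larvae = 1, strategy = "H1_single_bearing",
                      goal_bearings_deg = 90, kappa_goal = 50,
                      persistence_weight = 0,
                      turning_sd_model = list(intercept = 5, slope = 0),
                      rotation = list(type = "constant", rate_deg_s = 0),
                      seed = 30000 + k)
    d <- simulate_trajectory(cfg, 1)
    fa <- classify_deployment(d$trajectory, d$compass)
    abs(ang_diff(fa$bearing_cardinal_deg, 90))
  }, numeric(1))
  expect_true(all(errs < 5))
})

test_that("zero speed noise reproduces the age speed model exactly away from walls", {
  cfg <- sim_config(n_larvae = 1, ages_dph = 10,
                    strategy = "H1_single_bearing",
                    speed_model = list(intercept = 0.4, slope = 0.006,
                                       noise_sd = 0),
                    rotation = list(type = "constant", rate_deg_s = 0),
                    arena_radius_cm = 1e6, start_radius_frac = 1e-9,
                    trial_s = 300, seed = 17)
  d <- simulate_trajectory(cfg, 1)
  sp <- instantaneous_speeds(d$trajectory)
  expect_equal(sp, rep(0.4 + 0.006 * 10, length(sp)), tolerance = 1e-10)
})

test_that("H2 goals flip at the switch age and H4 draws goals from the mixture", {
  cfg2 <- sim_config(n_larvae = 30, strategy = "H2_condition_dependent",
                     goal_bearings_deg = c(90, 270), switch_age_dph = 12,
                     seed = 5)
  coh2 <- simulate_cohort(cfg2)
  expect_true(all(coh2$truth$goal_bearing_deg[coh2$truth$age_dph < 12] == 90))
  expect_true(all(coh2$truth$goal_bearing_deg[coh2$truth$age_dph >= 12] == 270))

  cfg4 <- sim_config(n_larvae = 200, strategy = "H4_mixed",
                     goal_bearings_deg = c(90, 270),
                     mixture_weights = c(0.5, 0.5), seed = 6)
  coh4 <- simulate_cohort(cfg4)
  share <- mean(coh4$truth$goal_bearing_deg == 90)
  expect_gt(share, 0.38)  # binomial band around 0.5 at n = 200
  expect_lt(share, 0.62)
})

test_that("H3 goals point from the deployment site toward the reef line", {
  cfg <- sim_config(n_larvae = 10, strategy = "H3_context_dependent", seed = 8)
  coh <- simulate_cohort(cfg)
  # deployments sit offshore (east) of a meridional reef: goals point west
  errs <- abs(ang_diff(coh$truth$goal_bearing_deg, 270))
  expect_true(all(errs < 45))
})

test_that("estimated cohort concentration increases with kappa and bearing recovery is unbiased", {
  grand <- function(kappa, seed) {
    cfg <- sim_config(n_larvae = 40, strategy = "H1_single_bearing",
                      goal_bearings_deg = 120, kappa_goal = kappa,
                      seed = seed)
    coh <- simulate_cohort(cfg)
    bearings <- vapply(coh$deployments, function(d) {
      classify_deployment(d$trajectory, d$compass)$bearing_cardinal_deg
    }, numeric(1))
    s <- second_order_rayleigh(bearings[!is.na(bearings)])
    c(r = s$r, err = ang_diff(s$mean_bearing_deg, 120))
  }
  out <- vapply(c(0.5, 1, 2), grand, numeric(2), seed = 314)
  expect_true(all(diff(out["r", ]) > 0))
  expect_true(all(abs(out["err", ]) < 5))
})

test_that("written cohort directories round-trip through the CSV readers", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(sim_config(n_larvae = 3, trial_s = 120, seed = 55))
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir,
    c("trajectories.csv", "compass.csv", "metadata.csv", "gps.csv",
      "truth.csv", "config.yml")))))
  trajs <- read_trajectories_csv(file.path(dir, "trajectories.csv"),
                                 acclimation_s = 0)
  expect_length(trajs, 3)
  expect_equal(trajs[["d002"]]$x_cm,
               round(coh$deployments[[2]]$trajectory$x_cm, 4))
  comp <- read_compass_csv(file.path(dir, "compass.csv"))
  expect_length(comp[["d001"]]$t_s, 120)
  meta <- read_metadata_csv(file.path(dir, "metadata.csv"))
  expect_equal(meta$age_dph, coh$truth$age_dph)
  gps <- read_gps_csv(file.path(dir, "gps.csv"))
  expect_equal(nrow(gps[["d003"]]), 3)
})
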