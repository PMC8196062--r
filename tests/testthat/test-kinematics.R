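deg2rad_test <- function(d) d * pi / 180

test_that("1 Hz subsampling counts ticks and recovers exact frame positions", {
  # 30 fps, 900 s, acclimation already removed
  t <- seq(0, 900 - 1 / 30, by = 1 / 30)
  raw <- trajectory("fps30", t, x_cm = rep(1, length(t)),
                    y_cm = rep(0, length(t)), acclimation_s = 0)
  sub <- subsample_1hz(raw)
  expect_length(sub$t_s, 900)

  # already-1 Hz input passes through unchanged
  one <- trajectory("hz1", 0:59, x_cm = sin(0:59), y_cm = cos(0:59),
                    acclimation_s = 0)
  sub1 <- subsample_1hz(one)
  expect_equal(sub1$x_cm, one$x_cm)
  expect_equal(sub1$t_s, one$t_s)

  # 5 fps with known integer-second positions: exact recovery
  t5 <- seq(0, 20, by = 0.2)
  x5 <- t5 / 10            # position encodes time
  raw5 <- trajectory("fps5", t5, x5, rep(0, length(t5)), acclimation_s = 0)
  sub5 <- subsample_1hz(raw5)
  expect_equal(sub5$x_cm, (0:20) / 10)

  # acclimation window removed
  acc <- trajectory("acc", 0:899, x_cm = rep(0, 900), y_cm = rep(1, 900),
                    acclimation_s = 300)
  expect_equal(range(subsample_1hz(acc)$t_s), c(300, 899))

  short <- trajectory("short", c(0, 0.5), c(0, 0), c(1, 1), acclimation_s = 0)
  expect_error(subsample_1hz(short), "< 2 s")
})

test_that("trajectory validation rejects bad input", {
  expect_error(trajectory("x", c(0, 0), c(1, 2), c(1, 2)), "strictly increasing")
  expect_error(trajectory("x", 0:1, c(0, 50), c(0, 0)), "outside")
  expect_error(trajectory("x", 0:1, c(0, NA), c(0, 0)), "missing")
})

test_that("instantaneous speeds are displacement over time step", {
  tr <- trajectory("sp", 0:1, c(0, 0.45), c(0, 0), acclimation_s = 0)
  expect_equal(instantaneous_speeds(tr), 0.45)
  still <- trajectory("still", 0:9, rep(1, 10), rep(2, 10), acclimation_s = 0)
  expect_equal(instantaneous_speeds(still), rep(0, 9))
  tr2 <- straight_traj(n = 11, speed = 0.6)
  expect_equal(mean(instantaneous_speeds(tr2)), 0.6)
  expect_length(instantaneous_speeds(tr2), 10)
})

test_that("turning angles: collinear is 0, right angle is 90, reversals are 180", {
  col <- trajectory("col", 0:2, c(0, 1, 2), c(0, 0, 0), acclimation_s = 0)
  expect_equal(as.numeric(turning_angles(col)), 0)
  ra <- trajectory("ra", 0:2, c(0, 1, 1), c(0, 0, 1), acclimation_s = 0)
  expect_equal(as.numeric(turning_angles(ra)), 90)
  rev <- trajectory("rev", 0:2, c(0, 1, 0), c(0, 0, 0), acclimation_s = 0)
  expect_equal(as.numeric(turning_angles(rev)), 180)
  # zero-length displacements skipped and counted
  paused <- trajectory("pause", 0:3, c(0, 1, 1, 2), c(0, 0, 0, 0),
                       acclimation_s = 0)
  ta <- turning_angles(paused)
  expect_equal(as.numeric(ta), 0)
  expect_equal(attr(ta, "n_zero_steps"), 1L)
  frozen <- trajectory("frozen", 0:3, rep(0, 4), rep(1, 4), acclimation_s = 0)
  expect_warning(ta0 <- turning_angles(frozen), "never moved")
  expect_length(ta0, 0)
})

test_that("turning angles are invariant to rotation and translation", {
  set.seed(3)
  n <- 50
  x <- cumsum(rnorm(n, 0, 0.3))
  y <- cumsum(rnorm(n, 0, 0.3))
  base <- trajectory("b", 0:(n - 1), x, y, arena_radius_cm = 1000,
                     acclimation_s = 0)
  th <- pi / 5
  rot <- trajectory("r", 0:(n - 1),
                    cos(th) * x - sin(th) * y + 3,
                    sin(th) * x + cos(th) * y - 2,
                    arena_radius_cm = 1000, acclimation_s = 0)
  expect_equal(as.numeric(turning_angles(rot)),
               as.numeric(turning_angles(base)), tolerance = 1e-9)
})

test_that("mean turning angle of a correlated walk matches the folded-normal mean", {
  # heading increments N(0, 30 deg): E|turn| = 30 * sqrt(2/pi)
  set.seed(21)
  cfg <- sim_config(n_larvae = 1, strategy = "H1_single_bearing",
                    kappa_goal = 1e9, persistence_weight = 1,
                    turning_sd_model = list(intercept = 30, slope = 0),
                    speed_model = list(intercept = 0.5, slope = 0,
                                       noise_sd = 0),
                    rotation = list(type = "constant", rate_deg_s = 0),
                    arena_radius_cm = 1e6, start_radius_frac = 1e-6,
                    trial_s = 3600, seed = 21)
  d <- simulate_trajectory(cfg, 1)
  ta <- turning_angles(d$trajectory)
  expect_equal(mean(ta), 30 * sqrt(2 / pi), tolerance = 0.06)
})

test_that("position bearings follow the compass convention and exclude the center", {
  up <- trajectory("up", 0:1, c(0, 5), c(5, 0), acclimation_s = 0)
  b <- position_bearings(up)
  expect_equal(b$angles_deg, c(0, 90))

  ring <- trajectory("ring", 0:7,
                     5 * sin(seq(0, 2 * pi, length.out = 9)[-9]),
                     5 * cos(seq(0, 2 * pi, length.out = 9)[-9]),
                     acclimation_s = 0)
  expect_gt(rayleigh_test(position_bearings(ring))$p_value, 0.999)

  near <- trajectory("near", 0:2, c(0.1, 0, 5), c(0.2, 5, 0),
                     acclimation_s = 0)
  bn <- position_bearings(near)
  expect_length(bn$angles_deg, 2)
  expect_equal(attr(bn, "n_center_excluded"), 1L)
  center <- trajectory("c", 0:1, c(0, 0.1), c(0, 0), acclimation_s = 0)
  expect_error(position_bearings(center), "center")
})

test_that("position bearings commute with frame rotation", {
  set.seed(9)
  n <- 40
  r <- runif(n, 1, 9)
  th <- runif(n, 0, 2 * pi)
  cc <- 73.2
  t0 <- trajectory("a", 0:(n - 1), r * sin(th), r * cos(th),
                   acclimation_s = 0)
  t1 <- trajectory("a", 0:(n - 1), r * sin(th + deg2rad_test(cc)),
                   r * cos(th + deg2rad_test(cc)), acclimation_s = 0)
  d <- ang_diff(position_bearings(t1)$angles_deg,
                position_bearings(t0)$angles_deg)
  expect_true(all(abs(d - cc) < 1e-8 | abs(d - cc + 360) < 1e-8))
})

test_that("pixel calibration rescales to the arena diameter", {
  px <- pixels_to_cm(c(0, 400), c(200, 200), arena_diameter_px = 400)
  expect_equal(px$x_cm, c(-10, 10))
  expect_equal(px$y_cm, c(0, 0))
})
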