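# shared fixtures built in code

# straight-line 1 Hz trajectory along +x, speed cm/s
straight_traj <- function(n = 10, speed = 0.5, id = "straight") {
  trajectory(id, t_s = 0:(n - 1), x_cm = speed * (0:(n - 1)) - 5,
             y_cm = rep(0, n), acclimation_s = 0)
}

# constant-heading compass
flat_compass <- function(n = 10, heading = 0) {
  compass_series(0:(n - 1), rep(heading, n))
}

# uniform positions in a disc as a 1 Hz trajectory
uniform_disc_traj <- function(n = 900, radius = 10, id = "unif") {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  trajectory(id, t_s = 0:(n - 1), x_cm = r * sin(th), y_cm = r * cos(th),
             arena_radius_cm = radius, acclimation_s = 0)
}

# Monte-Carlo Rayleigh p oracle: share of uniform samples with r >= r_obs
mc_rayleigh_p <- function(r_obs, n, n_draws = 1e5) {
  a <- matrix(stats::runif(n_draws * n, 0, 2 * pi), nrow = n_draws)
  r_draw <- sqrt(rowMeans(sin(a))^2 + rowMeans(cos(a))^2)
  mean(r_draw >= r_obs)
}

# shortest signed angular difference a - b in (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
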