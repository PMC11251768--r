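test_that("sensor noise has the configured Gaussian law", {
  cfg0 <- sensor_config(noise_sigma_fraction = 0)
  expect_identical(add_sensor_noise(1.23, cfg0, running_mean = 5), 1.23)
  cfg_mu <- sensor_config(noise_mu = 0.5, noise_sigma_fraction = 0)
  expect_equal(add_sensor_noise(2, cfg_mu, running_mean = 1), 2.5)
  cfg <- sensor_config(noise_sigma_fraction = 0.02)
  set.seed(1)
  draws <- add_sensor_noise(rep(0, 1e5), cfg, running_mean = 1)
  expect_equal(sd(draws), 0.02, tolerance = 0.02)
  expect_equal(mean(draws), 0, tolerance = 3 * 0.02 / sqrt(1e5))
})

test_that("detection is strictly above threshold and purely local", {
  pl <- new_plume(tiny_plume_cfg())
  w <- wind_state(turbulence_intensity = 0)
  noiseless <- sensor_config(detection_threshold = 0.01,
                             noise_sigma_fraction = 0)
  st <- list(position = c(0, 0, 0), rm_conc = NA_real_, rm_wind = NA_real_)
  # empty plume: no detection
  expect_false(sense(pl, w, st, noiseless, 1 / 75)$detected)
  # strong co-located puff: detection
  pl$puffs <- rbind(pl$puffs, c(0, 0, 0, 1e-2, 1, 0, 0, 0, 0))
  expect_true(sense(pl, w, st, noiseless, 1 / 75)$detected)
  # threshold exactly at the concentration: strict inequality, no detection
  conc <- concentration_at(pl, c(0, 0, 0))
  at <- sensor_config(detection_threshold = conc, noise_sigma_fraction = 0)
  expect_false(sense(pl, w, st, at, 1 / 75)$detected)
  # locality: puffs far outside any sensing radius change nothing
  pl2 <- pl
  pl2$puffs <- rbind(pl2$puffs,
                     c(0.9, 0.45, 0.45, 1e-4, 100, 0, 0, 0, 0))
  s1 <- sense(pl, w, st, noiseless, 1 / 75)
  s2 <- sense(pl2, w, st, noiseless, 1 / 75)
  expect_identical(s1$detected, s2$detected)
  expect_identical(s1$sensed_wind, s2$sensed_wind)
})

test_that("cast/surge decision rule follows the timer contract", {
  cfg <- agent_config()
  dt <- 1 / 75
  st <- list(mode = "s", timer = 0, cast_sign = 1, cast_phase = 0,
             cast_clock = 0, upwind = c(1, 0, 0))
  wind <- c(-0.25, 0, 0)
  # detection switches to surge and resets the timer
  d <- decide(st, TRUE, wind, cfg, dt)
  expect_identical(d$state$mode, "o")
  expect_equal(d$state$timer, cfg$surge_duration)
  # surge command points upwind
  expect_equal(d$command, cfg$surge_speed * c(1, 0, 0))
  # no detection for longer than surge_duration: back to casting
  st2 <- d$state
  for (i in seq_len(ceiling(cfg$surge_duration / dt) + 1L)) {
    d2 <- decide(st2, FALSE, wind, cfg, dt)
    st2 <- d2$state
  }
  expect_identical(st2$mode, "s")
  # casting command is crosswind: projection on upwind equals the drift
  expect_equal(sum(d2$command * c(1, 0, 0)), cfg$cast_upwind_drift)
})

test_that("acceleration clamp saturates exactly and caps speed", {
  dt <- 0.01
  v <- c(0, 0, 0)
  cmd <- c(1, 0, 0)
  out <- clamp_acceleration(v, cmd, max_acceleration = 50, dt = dt)
  expect_equal(sqrt(sum(out^2)) / dt, 50)
  # commanded equal to current: unchanged
  expect_equal(clamp_acceleration(cmd, cmd, 50, dt), cmd)
  # infinite acceleration recovers instant manoeuvring
  expect_equal(clamp_acceleration(v, cmd, Inf, dt), cmd)
  # max speed cap applies
  out2 <- clamp_acceleration(c(0.9, 0, 0), c(2, 0, 0), Inf, dt, max_speed = 1)
  expect_equal(sqrt(sum(out2^2)), 1)
})

test_that("flights are reproducible and respect the acceleration bound", {
  cfg <- pinned_config()
  f1 <- simulate_flight(cfg$plume, cfg$wind, cfg$agent, cfg$sensor,
                        seed = 5, warmup = 2)
  f2 <- simulate_flight(cfg$plume, cfg$wind, cfg$agent, cfg$sensor,
                        seed = 5, warmup = 2)
  expect_identical(f1$trajectory, f2$trajectory)
  expect_identical(f1$modes, f2$modes)
  # realized per-step acceleration never exceeds the configured cap
  pos <- as.matrix(f1$trajectory[, c("x", "y", "z")])
  v <- diff(pos) / f1$dt
  acc <- sqrt(rowSums(diff(v)^2)) / f1$dt
  expect_lte(max(acc), cfg$agent$max_acceleration + 1e-8)
  # speed cap holds too
  expect_lte(max(sqrt(rowSums(v^2))), cfg$agent$max_speed + 1e-8)
})

test_that("modes alternate exactly at the recorded switch indices", {
  cfg <- pinned_config()
  fl <- simulate_flight(cfg$plume, cfg$wind, cfg$agent, cfg$sensor,
                        seed = 21, warmup = cfg$warmup)
  m <- fl$modes
  changes <- which(m[-1] != m[-length(m)]) + 1L
  expect_identical(fl$switch_indices, changes)
  expect_true(all(m %in% c("s", "o")))
})

test_that("an agent released at the source succeeds immediately", {
  cfg <- pinned_config()
  agent <- cfg$agent
  agent$start_position <- cfg$plume$source_position
  fl <- simulate_flight(cfg$plume, cfg$wind, agent, cfg$sensor,
                        seed = 1, warmup = 0.2)
  expect_true(fl$success)
  expect_equal(nrow(fl$trajectory), 1L)
})

test_that("an infinite threshold produces a pure casting flight", {
  cfg <- pinned_config()
  sensor <- sensor_config(detection_threshold = Inf)
  fl <- simulate_flight(cfg$plume, cfg$wind, cfg$agent, sensor,
                        seed = 3, warmup = 1)
  expect_true(all(fl$modes == "s"))
  expect_false(fl$success)
})

test_that("mean_path averages and aligns flights as specified", {
  cfg <- pinned_config()
  fl <- simulate_flight(cfg$plume, cfg$wind, cfg$agent, cfg$sensor,
                        seed = 9, warmup = 2)
  # idempotence: the mean of identical flights is the flight itself
  mp <- mean_path(list(fl, fl, fl))
  expect_equal(mp$x, fl$trajectory$x, tolerance = 1e-12)
  # linearity: two straight lines from A average to the mid-line
  a <- line_traj(50, slope = c(1, 0, 0))
  b <- line_traj(50, slope = c(0, 1, 0))
  mid <- mean_path(list(a, b))
  expect_equal(mid$x, a$x / 2)
  expect_equal(mid$y, b$y / 2)
  # the mean of many casting flights is smoother than its members
  sensor <- sensor_config(detection_threshold = Inf)
  flights <- lapply(1:8, function(s) {
    simulate_flight(cfg$plume, cfg$wind, cfg$agent, sensor,
                    seed = s, warmup = 0.5)
  })
  mp2 <- mean_path(flights)
  vel_var <- function(tr) {
    v <- diff(as.matrix(tr[, c("x", "y", "z")]))
    sum(apply(v, 2, stats::var))
  }
  member_vars <- vapply(flights,
                        function(f) vel_var(f$trajectory), numeric(1))
  expect_lt(vel_var(mp2), min(member_vars))
  expect_error(mean_path(list()), "at least one")
})
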