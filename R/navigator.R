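#' Sensor configuration
#'
#' The agent carries a single odour sensor giving a binary detection (noisy
#' concentration strictly above `detection_threshold`) and a noisy reading of
#' the local wind vector. Gaussian noise is added to every sensed channel
#' with mean `noise_mu` and standard deviation
#' `noise_sigma_fraction * running mean of the input signal` — by default 2%
#' of the average input, with zero mean.
#'
#' @param detection_threshold Concentration threshold (same arbitrary units
#'   as [concentration_at()]); detection requires strictly greater.
#' @param noise_mu Additive noise mean (signal units), default 0.
#' @param noise_sigma_fraction Noise s.d. as a fraction of the running-average
#'   input signal, default 0.02; 0 gives noiseless sensing.
#' @param running_mean_tau Time constant (s) of the exponentially-weighted
#'   running mean that defines the "average input signal".
#' @return A `sensor_config` list.
#' @export
sensor_config <- function(detection_threshold = 25,
                          noise_mu = 0,
                          noise_sigma_fraction = 0.02,
                          running_mean_tau = 1) {
  stopifnot(is.finite(detection_threshold) || is.infinite(detection_threshold),
            detection_threshold > 0,
            is.finite(noise_mu),
            noise_sigma_fraction >= 0, running_mean_tau > 0)
  structure(list(detection_threshold = detection_threshold,
                 noise_mu = noise_mu,
                 noise_sigma_fraction = noise_sigma_fraction,
                 running_mean_tau = running_mean_tau),
            class = "sensor_config")
}

#' Agent configuration
#'
#' Kinematic and behavioural parameters of the memoryless cast-and-surge
#' navigator. The agent holds no map and no history: its only internal state
#' is the behavioural mode (surge = exploitation `"o"`, cast = exploration
#' `"s"`), a countdown timer and the casting sweep sign. A detection resets
#' the timer to `surge_duration` (so repeated detections extend surging
#' without storing any signal history); when the timer expires the agent
#' falls back to crosswind casting.
#'
#' None of these values are published quantities; they are simulator defaults
#' chosen so flights cross a 2 m working section in a plausible time at a
#' 0.25 m/s wind (see the methods vignette).
#'
#' @param max_speed Hard speed cap, m/s.
#' @param max_acceleration Acceleration cap, m/s^2; `Inf` recovers instant
#'   manoeuvring.
#' @param surge_speed Commanded upwind speed while surging, m/s.
#' @param cast_speed Commanded crosswind speed while casting, m/s.
#' @param surge_duration Timer reset value after a detection, s.
#' @param cast_period Time between casting sign flips, s.
#' @param cast_upwind_drift Small upwind speed component maintained while
#'   casting, m/s.
#' @param cast_vertical_amplitude Amplitude of the vertical velocity
#'   oscillation while casting, m/s.
#' @param success_radius Distance from the source at which the flight counts
#'   as successful, m.
#' @param max_flight_time Time limit per flight, s.
#' @param start_position Agent release point, metres.
#' @return An `agent_config` list.
#' @export
agent_config <- function(max_speed = 1.0,
                         max_acceleration = 8,
                         surge_speed = 0.335,
                         cast_speed = 0.7,
                         surge_duration = 3.0,
                         cast_period = 0.45,
                         cast_upwind_drift = 0.05,
                         cast_vertical_amplitude = 0.3,
                         success_radius = 0.1,
                         max_flight_time = 20,
                         start_position = c(0, -0.32, 0)) {
  stopifnot(max_speed > 0, max_acceleration > 0,
            surge_speed > 0, surge_speed <= max_speed,
            cast_speed > 0, cast_speed <= max_speed,
            surge_duration > 0, cast_period > 0,
            cast_upwind_drift >= 0, cast_vertical_amplitude >= 0,
            success_radius > 0, max_flight_time > 0,
            length(start_position) == 3L, all(is.finite(start_position)))
  structure(list(max_speed = max_speed,
                 max_acceleration = max_acceleration,
                 surge_speed = surge_speed,
                 cast_speed = cast_speed,
                 surge_duration = surge_duration,
                 cast_period = cast_period,
                 cast_upwind_drift = cast_upwind_drift,
                 cast_vertical_amplitude = cast_vertical_amplitude,
                 success_radius = success_radius,
                 max_flight_time = max_flight_time,
                 start_position = as.numeric(start_position)),
            class = "agent_config")
}

#' Add multiplicative-scale Gaussian sensor noise
#'
#' Returns `signal + N(noise_mu, noise_sigma_fraction * running_mean)`,
#' vectorized over `signal` (one independent draw per element). With
#' `noise_sigma_fraction = 0` and `noise_mu = 0` the signal is returned
#' unchanged, exactly.
#'
#' @param signal Numeric vector of sensed values.
#' @param cfg A [sensor_config()].
#' @param running_mean Non-negative scalar: the running average of the input
#'   signal that sets the noise scale.
#' @return Noisy signal, same length as `signal`.
#' @export
add_sensor_noise <- function(signal, cfg, running_mean) {
  if (!is.finite(running_mean) || running_mean < 0) {
    stop("`running_mean` must be a non-negative finite scalar")
  }
  s <- cfg$noise_sigma_fraction * running_mean
  if (s == 0 && cfg$noise_mu == 0) return(signal)
  signal + stats::rnorm(length(signal), mean = cfg$noise_mu, sd = s)
}

#' Sense the local odour and wind
#'
#' Strictly local sensing: the agent observes only the concentration and the
#' instantaneous wind *at its own position*, both corrupted by Gaussian noise
#' scaled by exponentially-weighted running means of the respective inputs
#' (concentration magnitude for the odour channel, wind speed for all three
#' wind components). Detection is `noisy concentration > threshold`
#' (strict inequality).
#'
#' @param plume A `puff_plume`.
#' @param wind A [wind_state()].
#' @param state Agent state list with at least `position`, `rm_conc`,
#'   `rm_wind` (running means; `NA` before the first observation).
#' @param cfg A [sensor_config()].
#' @param dt Time step used to advance the running means, seconds.
#' @return A list with `detected` (logical), `sensed_wind` (3-vector) and the
#'   updated `state`.
#' @export
sense <- function(plume, wind, state, cfg, dt) {
  conc <- concentration_at(plume, state$position)
  w <- instantaneous_wind(wind)
  speed <- sqrt(sum(w * w))
  a <- dt / cfg$running_mean_tau
  state$rm_conc <- if (is.na(state$rm_conc)) conc else
    state$rm_conc + a * (conc - state$rm_conc)
  state$rm_wind <- if (is.na(state$rm_wind)) speed else
    state$rm_wind + a * (speed - state$rm_wind)
  noisy_conc <- add_sensor_noise(conc, cfg, state$rm_conc)
  sensed_wind <- add_sensor_noise(w, cfg, state$rm_wind)
  list(detected = noisy_conc > cfg$detection_threshold,
       sensed_wind = sensed_wind,
       state = state)
}

#' Cast/surge decision rule
#'
#' The behavioural core of the navigator. On detection the agent (re)enters
#' SURGE (`"o"`) with the timer reset to `surge_duration` and commands
#' `surge_speed` directly upwind (against the sensed wind). Without a
#' detection the timer counts down; while it is positive the agent keeps
#' surging, and when it reaches zero the agent switches to CAST (`"s"`):
#' crosswind sweeps at `cast_speed` in the horizontal plane, the sweep sign
#' flipping every `cast_period` seconds, plus a small configured upwind drift
#' and a bounded vertical oscillation. If the sensed wind is too weak to
#' define a direction, the last known upwind direction is reused.
#'
#' @param state Agent state list (fields `mode`, `timer`, `cast_sign`,
#'   `cast_phase`, `cast_clock`, `upwind`).
#' @param detected Logical: binary odour detection this step.
#' @param sensed_wind Noisy local wind, 3-vector.
#' @param cfg An [agent_config()].
#' @param dt Time step, seconds.
#' @return List with `command` (commanded velocity, 3-vector) and the updated
#'   `state` (mode, timer, casting bookkeeping).
#' @export
decide <- function(state, detected, sensed_wind, cfg, dt) {
  u <- -sensed_wind
  nu <- sqrt(sum(u * u))
  if (nu > 1e-9) state$upwind <- u / nu
  u <- state$upwind
  if (detected) {
    state$mode <- "o"
    state$timer <- cfg$surge_duration
  } else if (state$mode == "o") {
    state$timer <- max(0, state$timer - dt)
    if (state$timer == 0) state$mode <- "s"
  }
  if (state$mode == "o") {
    command <- cfg$surge_speed * u
  } else {
    state$cast_phase <- state$cast_phase + dt
    state$cast_clock <- state$cast_clock + dt
    if (state$cast_phase >= cfg$cast_period) {
      state$cast_sign <- -state$cast_sign
      state$cast_phase <- 0
    }
    cw <- c(-u[2L], u[1L], 0)
    ncw <- sqrt(sum(cw * cw))
    cw <- if (ncw > 1e-9) cw / ncw else c(0, 1, 0)
    vert <- cfg$cast_vertical_amplitude *
      sin(2 * pi * state$cast_clock / (2.7 * cfg$cast_period))
    command <- cfg$cast_speed * state$cast_sign * cw +
      cfg$cast_upwind_drift * u + c(0, 0, vert)
  }
  list(command = command, state = state)
}

#' Bound the change in velocity by a maximum acceleration
#'
#' The commanded velocity change is truncated so that `|dv| / dt` never
#' exceeds `max_acceleration`; the result is additionally capped at
#' `max_speed`. With `max_acceleration = Inf` the commanded velocity is
#' adopted instantly (the original unbounded behaviour).
#'
#' @param current_velocity,commanded_velocity 3-vectors, m/s.
#' @param max_acceleration Scalar cap, m/s^2.
#' @param dt Time step, s (> 0).
#' @param max_speed Optional speed cap, m/s (default `Inf`).
#' @return The realized new velocity, a 3-vector.
#' @export
clamp_acceleration <- function(current_velocity, commanded_velocity,
                               max_acceleration, dt, max_speed = Inf) {
  if (dt <= 0) stop("`dt` must be positive")
  dv <- commanded_velocity - current_velocity
  ndv <- sqrt(sum(dv * dv))
  dv_max <- max_acceleration * dt
  if (is.finite(dv_max) && ndv > dv_max) dv <- dv * (dv_max / ndv)
  v <- current_velocity + dv
  nv <- sqrt(sum(v * v))
  if (nv > max_speed) v <- v * (max_speed / nv)
  v
}

unit_or <- function(v, fallback) {
  n <- sqrt(sum(v * v))
  if (n > 1e-12) v / n else fallback
}

#' Simulate one cast-and-surge flight
#'
#' Steps the wind, the plume and the agent at the plume `dt` until the agent
#' comes within `success_radius` of the source, leaves the domain (failure)
#' or exceeds `max_flight_time`. The plume is spun up for `warmup` seconds
#' before the agent is released so the agent starts in a developed plume.
#' The per-step ground-truth behavioural mode (`"s"` exploration /
#' `"o"` exploitation) is recorded, giving labelled trajectories for
#' benchmarking the exploration--exploitation segmentation. The whole run is
#' reproducible from `seed`.
#'
#' @param plume_cfg A [plume_config()].
#' @param wind_cfg A [wind_state()] (used as the initial wind state).
#' @param agent_cfg An [agent_config()].
#' @param sensor_cfg A [sensor_config()].
#' @param seed Integer seed for the run.
#' @param warmup Plume spin-up time before release, seconds.
#' @return A `flight_record`: list with `trajectory` (data.frame t, x, y, z),
#'   `modes` (per-sample labels), `switch_indices`, `success`, `seed`,
#'   `dt`, and the configs used.
#' @export
simulate_flight <- function(plume_cfg, wind_cfg = wind_state(),
                            agent_cfg = agent_config(),
                            sensor_cfg = sensor_config(),
                            seed = 1L, warmup = 10) {
  stopifnot(inherits(plume_cfg, "plume_config"),
            inherits(agent_cfg, "agent_config"),
            inherits(sensor_cfg, "sensor_config"))
  set.seed(seed)
  dt <- plume_cfg$dt
  wind <- wind_cfg
  plume <- new_plume(plume_cfg)
  t <- 0
  n_warm <- round(warmup / dt)
  for (i in seq_len(n_warm)) {
    wind <- step_wind(wind, dt)
    plume <- release_puffs(plume, t, dt)
    plume <- advect_and_grow(plume, wind, dt)
    t <- t + dt
  }

  src <- plume_cfg$source_position
  b <- plume_cfg$domain_bounds
  state <- list(position = agent_cfg$start_position,
                velocity = c(0, 0, 0),
                mode = "s", timer = 0,
                cast_sign = 1, cast_phase = 0, cast_clock = 0,
                upwind = unit_or(-wind_cfg$mean_velocity, c(1, 0, 0)),
                rm_conc = NA_real_, rm_wind = NA_real_)
  n_max <- round(agent_cfg$max_flight_time / dt)
  pos <- matrix(NA_real_, nrow = n_max + 1L, ncol = 3L)
  modes <- character(n_max + 1L)
  pos[1L, ] <- state$position
  modes[1L] <- state$mode
  success <- sqrt(sum((state$position - src)^2)) <= agent_cfg$success_radius
  n_rec <- 1L
  if (!success) {
    for (i in seq_len(n_max)) {
      wind <- step_wind(wind, dt)
      plume <- release_puffs(plume, t, dt)
      plume <- advect_and_grow(plume, wind, dt)
      sr <- sense(plume, wind, state, sensor_cfg, dt)
      state <- sr$state
      dec <- decide(state, sr$detected, sr$sensed_wind, agent_cfg, dt)
      state <- dec$state
      cmd <- dec$command
      ncmd <- sqrt(sum(cmd * cmd))
      if (ncmd > agent_cfg$max_speed) cmd <- cmd * (agent_cfg$max_speed / ncmd)
      state$velocity <- clamp_acceleration(state$velocity, cmd,
                                           agent_cfg$max_acceleration, dt,
                                           agent_cfg$max_speed)
      state$position <- state$position + state$velocity * dt
      t <- t + dt
      n_rec <- n_rec + 1L
      pos[n_rec, ] <- state$position
      modes[n_rec] <- state$mode
      if (sqrt(sum((state$position - src)^2)) <= agent_cfg$success_radius) {
        success <- TRUE
        break
      }
      p <- state$position
      if (p[1L] < b[1L, 1L] || p[1L] > b[2L, 1L] ||
          p[2L] < b[1L, 2L] || p[2L] > b[2L, 2L] ||
          p[3L] < b[1L, 3L] || p[3L] > b[2L, 3L]) {
        break
      }
    }
  }
  pos <- pos[seq_len(n_rec), , drop = FALSE]
  modes <- modes[seq_len(n_rec)]
  traj <- data.frame(t = dt * (seq_len(n_rec) - 1L),
                     x = pos[, 1L], y = pos[, 2L], z = pos[, 3L])
  switches <- which(modes[-1L] != modes[-length(modes)]) + 1L
  structure(list(trajectory = traj,
                 modes = modes,
                 switch_indices = switches,
                 success = success,
                 seed = seed,
                 dt = dt,
                 configs = list(plume = plume_cfg, wind = wind_cfg,
                                agent = agent_cfg, sensor = sensor_cfg)),
            class = "flight_record")
}

#' @export
print.flight_record <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat("<flight_record>", n, "samples (", sprintf("%.2f", x$trajectory$t[n]),
      "s ),", length(x$switch_indices), "mode switches,",
      if (x$success) "SUCCESS" else "no success", "\n")
  invisible(x)
}

#' Average route over a batch of flights
#'
#' Flights of different durations are aligned on normalized time: each
#' trajectory is linearly resampled to the length of the longest flight, then
#' positions are averaged per time index. The result represents the
#' "principal" behaviour of the batch, smoothing out run-to-run stochasticity.
#'
#' @param flights A non-empty list of `flight_record`s (or data.frames with
#'   columns t, x, y, z) sharing the same sampling interval.
#' @return A data.frame trajectory (t, x, y, z) with the longest flight's
#'   length.
#' @export
mean_path <- function(flights) {
  if (length(flights) == 0L) stop("`flights` must contain at least one flight")
  trajs <- lapply(flights, function(f) {
    if (inherits(f, "flight_record")) f$trajectory else f
  })
  dts <- vapply(trajs, function(tr) tr$t[2L] - tr$t[1L], numeric(1))
  if (length(dts) > 1L && any(abs(dts - dts[1L]) > 1e-9)) {
    stop("all flights must share the same sampling interval")
  }
  L <- max(vapply(trajs, nrow, integer(1)))
  out_u <- seq(0, 1, length.out = L)
  acc <- matrix(0, nrow = L, ncol = 3L)
  for (tr in trajs) {
    n <- nrow(tr)
    u <- if (n > 1L) seq(0, 1, length.out = n) else c(0, 1)
    for (j in 1:3) {
      y <- tr[[c("x", "y", "z")[j]]]
      if (n == 1L) y <- rep(y, 2L)
      acc[, j] <- acc[, j] + stats::approx(u, y, xout = out_u)$y
    }
  }
  acc <- acc / length(trajs)
  data.frame(t = dts[1L] * (seq_len(L) - 1L),
             x = acc[, 1L], y = acc[, 2L], z = acc[, 3L])
}
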