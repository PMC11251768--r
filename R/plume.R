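#' Configuration of the puff-based pheromone plume
#'
#' The plume is a collection of discrete Gaussian "puffs" (odour pockets)
#' released from a point source at a fixed frequency, advected by the
#' instantaneous wind plus per-puff turbulent jitter, and growing by
#' diffusion (`sigma^2` increases linearly in time). Puff mass is conserved:
#' as a puff spreads its peak concentration dilutes but its integral stays Q.
#'
#' Coordinates are metres in a right-handed frame with the origin at the agent
#' release point; the source default `(2, 0, 0)` places it 2 m upwind.
#'
#' @param source_position Source location, length-3, metres.
#' @param puff_frequency Release frequency in puffs per second (> 0); the
#'   frequency-sensitivity benchmark sweeps integer values 1..9.
#' @param initial_spread Initial Gaussian sigma of a puff, metres.
#' @param growth_rate Diffusive growth rate of sigma^2, m^2/s.
#' @param domain_bounds 2 x 3 matrix, rows `lower` and `upper`: puffs leaving
#'   the box are retired.
#' @param dt Simulation step, seconds; default 1/75 s matching a 75 Hz
#'   trajectory sampling convention.
#' @param release_schedule `"deterministic"` releases a puff every
#'   `1/puff_frequency` seconds; `"poisson"` draws the per-step count from a
#'   Poisson law with the same rate.
#' @param puff_strength Odour mass Q per puff, arbitrary units.
#' @param jitter_fraction Scale of per-puff velocity jitter relative to the
#'   shared wind fluctuation r.m.s. (dimensionless; 1 means the per-puff
#'   stationary r.m.s. equals `turbulence_intensity * |mean wind|`).
#' @return A `plume_config` list.
#' @export
plume_config <- function(source_position = c(2, 0, 0),
                         puff_frequency = 1,
                         initial_spread = 0.030,
                         growth_rate = 3e-4,
                         domain_bounds = rbind(lower = c(-0.6, -0.5, -0.5),
                                               upper = c(2.2, 0.5, 0.5)),
                         dt = 1 / 75,
                         release_schedule = c("deterministic", "poisson"),
                         puff_strength = 1,
                         jitter_fraction = 1) {
  release_schedule <- match.arg(release_schedule)
  domain_bounds <- as.matrix(domain_bounds)
  stopifnot(length(source_position) == 3L, all(is.finite(source_position)),
            is.finite(puff_frequency), puff_frequency > 0,
            initial_spread > 0, growth_rate >= 0,
            nrow(domain_bounds) == 2L, ncol(domain_bounds) == 3L,
            all(domain_bounds[1L, ] < domain_bounds[2L, ]),
            dt > 0, puff_strength > 0, jitter_fraction >= 0)
  structure(
    list(source_position = as.numeric(source_position),
         puff_frequency = puff_frequency,
         initial_spread = initial_spread,
         growth_rate = growth_rate,
         domain_bounds = domain_bounds,
         dt = dt,
         release_schedule = release_schedule,
         puff_strength = puff_strength,
         jitter_fraction = jitter_fraction),
    class = "plume_config")
}

#' Create an empty plume
#'
#' @param config A [plume_config()].
#' @return An object of class `puff_plume` holding the puff table (centre,
#'   sigma^2, strength, birth time, per-puff jitter velocity) and the release
#'   counter.
#' @export
new_plume <- function(config) {
  if (!inherits(config, "plume_config")) stop("`config` must be a plume_config")
  structure(
    list(config = config,
         puffs = matrix(numeric(0), nrow = 0L, ncol = 9L,
                        dimnames = list(NULL, c("x", "y", "z", "sigma2", "Q",
                                                "birth", "jx", "jy", "jz"))),
         released = 0L),
    class = "puff_plume")
}

#' Release new puffs during a time step
#'
#' Under the deterministic schedule, release times are `i / puff_frequency`
#' for i = 0, 1, 2, ...; all releases falling in `[t, t + dt)` are emitted
#' (tracked by a counter, so repeated stepping never duplicates or skips a
#' release). Under the Poisson schedule the number of releases in the step is
#' `rpois(1, puff_frequency * dt)`. New puffs start at the source with the
#' configured initial spread.
#'
#' @param plume A `puff_plume`.
#' @param t Current time, seconds.
#' @param dt Step length, seconds (> 0).
#' @return The plume with any new puffs appended.
#' @export
release_puffs <- function(plume, t, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  cfg <- plume$config
  if (cfg$release_schedule == "deterministic") {
    # largest i with i / f < t + dt  (tolerance guards float drift)
    i_max <- floor((t + dt) * cfg$puff_frequency * (1 + 1e-12) - 1e-9)
    n_new <- max(0L, as.integer(i_max) + 1L - plume$released)
  } else {
    n_new <- stats::rpois(1L, cfg$puff_frequency * dt)
  }
  if (n_new > 0L) {
    new_rows <- cbind(
      matrix(cfg$source_position, nrow = n_new, ncol = 3L, byrow = TRUE),
      cfg$initial_spread^2, cfg$puff_strength, t,
      0, 0, 0)
    plume$puffs <- rbind(plume$puffs, new_rows)
    plume$released <- plume$released + n_new
  }
  plume
}

#' Advect and grow all puffs over one time step
#'
#' Each puff centre moves by `(instantaneous wind + per-puff jitter) * dt`.
#' The per-puff jitter is an independent OU velocity with the same
#' correlation time as the wind fluctuation and stationary r.m.s.
#' `jitter_fraction * turbulence_intensity * |mean wind|`, so nearby puffs
#' decorrelate and the plume disperses into distinct pockets rather than a
#' coherent filament. Spread grows as `sigma^2 <- sigma^2 + growth_rate * dt`
#' (never decreases); puffs whose centres leave the domain box are retired.
#'
#' @param plume A `puff_plume`.
#' @param wind A [wind_state()] supplying the instantaneous wind and the
#'   turbulence parameters for the jitter.
#' @param dt Step length, seconds (> 0).
#' @return The updated plume.
#' @export
advect_and_grow <- function(plume, wind, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  np <- nrow(plume$puffs)
  if (np == 0L) return(plume)
  cfg <- plume$config
  p <- plume$puffs
  w <- instantaneous_wind(wind)
  sj <- cfg$jitter_fraction * wind$turbulence_intensity *
    sqrt(sum(wind$mean_velocity^2))
  if (sj > 0) {
    a <- exp(-dt / wind$correlation_time)
    p[, 7:9] <- p[, 7:9, drop = FALSE] * a +
      sj * sqrt(1 - a * a) * matrix(stats::rnorm(3L * np), nrow = np)
  }
  p[, 1L] <- p[, 1L] + (w[1L] + p[, 7L]) * dt
  p[, 2L] <- p[, 2L] + (w[2L] + p[, 8L]) * dt
  p[, 3L] <- p[, 3L] + (w[3L] + p[, 9L]) * dt
  p[, 4L] <- p[, 4L] + cfg$growth_rate * dt
  b <- cfg$domain_bounds
  keep <- p[, 1L] >= b[1L, 1L] & p[, 1L] <= b[2L, 1L] &
    p[, 2L] >= b[1L, 2L] & p[, 2L] <= b[2L, 2L] &
    p[, 3L] >= b[1L, 3L] & p[, 3L] <= b[2L, 3L]
  plume$puffs <- p[keep, , drop = FALSE]
  plume
}

#' Odour concentration at a point
#'
#' Superposition of 3D Gaussian puffs:
#' `sum_j Q_j / ((2*pi)^(3/2) sigma_j^3) * exp(-|x - c_j|^2 / (2 sigma_j^2))`.
#' Non-negative everywhere, continuous in the query point, and exactly zero
#' for an empty plume.
#'
#' @param plume A `puff_plume`.
#' @param point Length-3 numeric query position, metres.
#' @return Scalar concentration (arbitrary odour units, >= 0).
#' @export
concentration_at <- function(plume, point) {
  if (length(point) != 3L || !all(is.finite(point))) {
    stop("`point` must be a finite 3-vector")
  }
  p <- plume$puffs
  if (nrow(p) == 0L) return(0)
  r2 <- (p[, 1L] - point[1L])^2 + (p[, 2L] - point[2L])^2 +
    (p[, 3L] - point[3L])^2
  s2 <- p[, 4L]
  sum(p[, 5L] * (2 * pi)^(-1.5) * s2^(-1.5) * exp(-r2 / (2 * s2)))
}

#' Snapshot the current puff table
#'
#' @param plume A `puff_plume`.
#' @param t Time stamp for the snapshot, seconds.
#' @return A data.frame with columns t, puff_id, x, y, z, sigma, Q suitable
#'   for CSV dumping.
#' @export
plume_snapshot <- function(plume, t = NA_real_) {
  p <- plume$puffs
  data.frame(t = rep(t, nrow(p)),
             puff_id = seq_len(nrow(p)),
             x = p[, 1L], y = p[, 2L], z = p[, 3L],
             sigma = sqrt(p[, 4L]), Q = p[, 5L])
}

#' @export
print.puff_plume <- function(x, ...) {
  cat("<puff_plume>", nrow(x$puffs), "active puffs,",
      x$released, "released;",
      "frequency", x$config$puff_frequency, "/s\n")
  invisible(x)
}
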