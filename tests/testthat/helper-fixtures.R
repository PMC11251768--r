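# Shared fixtures, generated in code.

# straight-line trajectory with slope `c_per_sample` per coordinate step
line_traj <- function(n, slope = c(1, 2, 3), dt = 1 / 75) {
  i <- seq_len(n) - 1L
  data.frame(t = i * dt,
             x = slope[1] * i, y = slope[2] * i, z = slope[3] * i)
}

# two-regime trajectory: constant velocity then isotropic Gaussian jitter
# around a fixed point; the construction changepoint is `n1` (sample index)
two_regime_traj <- function(n1 = 250, n2 = 250, drift = c(0.02, 0, 0),
                            noise_sd = 0.05, seed = 1, dt = 1 / 75) {
  set.seed(seed)
  p1 <- t(sapply(seq_len(n1) - 1L, function(i) drift * i))
  anchor <- drift * (n1 - 1L)
  p2 <- matrix(rep(anchor, n2), ncol = 3, byrow = TRUE) +
    matrix(rnorm(3 * n2, sd = noise_sd), ncol = 3)
  pos <- rbind(p1, p2)
  data.frame(t = dt * (seq_len(n1 + n2) - 1L),
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

# small random walk trajectory for generic property tests
rw_traj <- function(n, seed = 1, sd = 0.02, dt = 1 / 75) {
  set.seed(seed)
  pos <- apply(matrix(rnorm(3 * n, sd = sd), ncol = 3), 2L, cumsum)
  data.frame(t = dt * (seq_len(n) - 1L),
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

# tiny plume configuration for fast unit tests
tiny_plume_cfg <- function(...) {
  plume_config(source_position = c(1, 0, 0),
               domain_bounds = rbind(lower = c(-0.5, -0.5, -0.5),
                                     upper = c(1.2, 0.5, 0.5)),
               ...)
}

# exhaustive-search oracle for the GA: enumerate all feasible breakpoint
# sets for k segments over m velocity samples and return the best
# |phase-signed objective| (independent of the GA code path)
brute_force_best <- function(v, k, min_len = 5L) {
  m <- nrow(v)
  score_seg <- function(a, b) {
    seg <- v[(a + 1L):b, , drop = FALSE]
    mu <- colMeans(seg)
    sum(sweep(seg, 2, mu)^2) / (2 * pi * (b - a))
  }
  best <- -Inf
  best_bp <- NULL
  combs <- utils::combn(m - 1L, k - 1L)
  for (ci in seq_len(ncol(combs))) {
    bp <- combs[, ci]
    edges <- c(0L, bp, m)
    if (any(diff(edges) < min_len)) next
    sgn <- rep_len(c(1, -1), k)
    J <- sum(sgn * mapply(score_seg, edges[-(k + 1L)], edges[-1L]))
    if (abs(J) > best) {
      best <- abs(J)
      best_bp <- bp
    }
  }
  list(objective = best, breakpoints = best_bp)
}
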