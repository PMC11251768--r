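#' Per-sample velocity by the five-point stencil
#'
#' Applies, componentwise and verbatim, the stencil
#' `v_i = (-l_{i-2} + 8 l_{i-1} - 8 l_{i+1} + l_{i+2}) / 12`
#' to the position sequence. Note that this expression is the *negative* of
#' the standard five-point first-derivative stencil and carries no division
#' by the sampling interval, so the resulting "velocities" are in metres per
#' sample with a flipped sign. It is kept literally because everything
#' downstream (the exploration score) uses only the dispersion of deviations
#' from the segment mean, which is invariant to a common sign and scale.
#'
#' @param traj A trajectory: data.frame with columns x, y, z (and optionally
#'   t, which must be uniformly spaced), or an n x 3 numeric matrix, or a
#'   `flight_record`.
#' @return An `(n - 4) x 3` matrix of velocity vectors; row i corresponds to
#'   trajectory sample i + 2. Attribute `offset` (= 2) records the number of
#'   samples trimmed at each end.
#' @export
compute_velocity <- function(traj) {
  l <- as_position_matrix(traj, check_uniform = TRUE)
  n <- nrow(l)
  if (n < 5L) stop("trajectory must have at least 5 samples")
  i <- 3:(n - 2L)
  v <- (-l[i - 2L, , drop = FALSE] + 8 * l[i - 1L, , drop = FALSE] -
          8 * l[i + 1L, , drop = FALSE] + l[i + 2L, , drop = FALSE]) / 12
  attr(v, "offset") <- 2L
  v
}

as_position_matrix <- function(traj, check_uniform = FALSE) {
  if (inherits(traj, "flight_record")) traj <- traj$trajectory
  if (is.data.frame(traj)) {
    if (!all(c("x", "y", "z") %in% names(traj))) {
      stop("trajectory data.frame needs columns x, y, z")
    }
    if (check_uniform && "t" %in% names(traj) && nrow(traj) > 2L) {
      dts <- diff(traj$t)
      if (max(dts) - min(dts) > 1e-6 * max(abs(dts))) {
        stop("trajectory must be uniformly sampled")
      }
    }
    traj <- cbind(traj$x, traj$y, traj$z)
  }
  m <- as.matrix(traj)
  if (ncol(m) != 3L) stop("positions must be 3-dimensional")
  storage.mode(m) <- "double"
  m
}

#' Exploration score of a velocity segment
#'
#' The dispersion of velocity vectors about the segment's mean direction:
#' `(1 / (2*pi)) * sum_i |v_i - vbar|^2 / duration`, where `vbar` is the
#' segment mean velocity and `duration` is the segment length counted in
#' samples. High values mean the motion keeps changing direction (casting);
#' near-zero values mean the velocities align towards a central direction
#' (surging). The score is invariant to adding a constant vector to all
#' velocities and scales quadratically with velocity magnitude.
#'
#' @param velocities Numeric matrix, one velocity vector per row (any
#'   dimension; 3 columns in normal use).
#' @param duration Segment length `t_e - t_s` in samples; defaults to the
#'   number of velocity rows.
#' @return A non-negative scalar.
#' @export
exploration_score <- function(velocities, duration = NULL) {
  if (is.vector(velocities)) velocities <- matrix(velocities, ncol = 1L)
  v <- as.matrix(velocities)
  if (nrow(v) == 0L) stop("empty velocity segment")
  if (is.null(duration)) duration <- nrow(v)
  if (duration <= 0) stop("`duration` must be positive")
  vbar <- colMeans(v)
  ss <- sum(sweep(v, 2L, vbar)^2)
  ss / (2 * pi * duration)
}

#' Alternating-label segmentation objective
#'
#' Sums the per-segment exploration scores with a sign per label. The
#' `convention` argument selects which label takes the positive sign:
#' `"exploration_positive"` (the default: exploration `"s"` segments
#' contribute `+score`, exploitation `"o"` segments `-score`, so the optimum
#' concentrates high-dispersion casting into `"s"` segments) or
#' `"exploitation_positive"` (the mirrored reading, `+` on `"o"`). The two
#' conventions are exact negations for a fixed labelling, so the optimal
#' breakpoints are the same under either; only the labels swap. Labels must
#' strictly alternate.
#'
#' @param traj Trajectory (see [compute_velocity()]).
#' @param segmentation An `ee_segmentation` or a list with `breakpoints`
#'   (strictly increasing velocity-sample indices, possibly empty) and
#'   `labels` (one `"s"`/`"o"` per segment).
#' @param convention `"exploration_positive"` or `"exploitation_positive"`.
#' @return The signed objective, a scalar.
#' @export
objective <- function(traj, segmentation,
                      convention = c("exploration_positive",
                                     "exploitation_positive")) {
  convention <- match.arg(convention)
  v <- compute_velocity(traj)
  bp <- segmentation$breakpoints
  labels <- segmentation$labels
  k <- length(labels)
  if (length(bp) != k - 1L) {
    stop("need exactly one more label than breakpoints")
  }
  if (k > 1L && any(labels[-1L] == labels[-k])) {
    stop("segment labels must strictly alternate")
  }
  m <- nrow(v)
  edges <- c(0L, as.integer(bp), m)
  if (any(diff(edges) <= 0L)) stop("breakpoints must be strictly increasing interior indices")
  pos_label <- if (convention == "exploration_positive") "s" else "o"
  total <- 0
  for (j in seq_len(k)) {
    seg <- v[(edges[j] + 1L):edges[j + 1L], , drop = FALSE]
    sc <- exploration_score(seg)
    total <- total + if (labels[j] == pos_label) sc else -sc
  }
  total
}

#' Genetic-algorithm configuration
#'
#' @param population_size Population size (alpha), much greater than 1.
#' @param royalty_fraction Fraction beta of the population copied unchanged
#'   into the next generation (elitism); `ceiling(alpha * beta)` must be at
#'   least 1.
#' @param generations Number of generations (zeta).
#' @param mutation_probability Probability that an offspring receives one
#'   +/-1 breakpoint mutation (default 1: every offspring).
#' @param crossover_probability Probability that a selected pair undergoes
#'   one-point crossover (applies only when there are at least 3
#'   breakpoints, as the crossover cut point requires it).
#' @param k_max Largest number of segments tried by [segment_trajectory()]
#'   (the "arbitrary large" upper bound z).
#' @param min_segment_length Minimum samples per segment; segments shorter
#'   than the stencil support are meaningless.
#' @param seed Optional integer seed; when set, [ga_fit()] and
#'   [segment_trajectory()] are fully reproducible.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100L,
                      royalty_fraction = 0.1,
                      generations = 200L,
                      mutation_probability = 1,
                      crossover_probability = 0.7,
                      k_max = 30L,
                      min_segment_length = 5L,
                      seed = NULL) {
  stopifnot(population_size >= 2, royalty_fraction > 0, royalty_fraction <= 1,
            generations >= 1, mutation_probability > 0,
            mutation_probability <= 1,
            crossover_probability >= 0, crossover_probability <= 1,
            k_max >= 2, min_segment_length >= 1,
            ceiling(population_size * royalty_fraction) >= 1)
  structure(list(population_size = as.integer(population_size),
                 royalty_fraction = royalty_fraction,
                 generations = as.integer(generations),
                 mutation_probability = mutation_probability,
                 crossover_probability = crossover_probability,
                 k_max = as.integer(k_max),
                 min_segment_length = as.integer(min_segment_length),
                 seed = seed),
            class = "ga_config")
}

#' Mutate one breakpoint by +/-1
#'
#' A uniformly chosen breakpoint is shifted up or down by one with equal
#' probability. If the shift would violate strict increase or the minimum
#' segment length, the draw is repeated (bounded retries) and finally the
#' individual is returned unchanged.
#'
#' @param breakpoints Strictly increasing integer vector of interior
#'   velocity-sample indices.
#' @param n_velocity Number of velocity samples the breakpoints partition.
#' @param min_segment_length Minimum samples per segment.
#' @param retries Number of redraws after an infeasible shift.
#' @return A feasible breakpoint vector differing from the input in at most
#'   one coordinate by exactly 1.
#' @export
mutate_breakpoints <- function(breakpoints, n_velocity,
                               min_segment_length = 5L, retries = 3L) {
  k1 <- length(breakpoints)
  if (k1 < 1L) stop("need at least one breakpoint")
  ml <- min_segment_length
  for (r in seq_len(retries + 1L)) {
    j <- sample.int(k1, 1L)
    v <- breakpoints[j] + sample(c(-1L, 1L), 1L)
    left <- if (j > 1L) breakpoints[j - 1L] else 0L
    right <- if (j < k1) breakpoints[j + 1L] else n_velocity
    if (v - left >= ml && right - v >= ml) {
      breakpoints[j] <- v
      return(breakpoints)
    }
  }
  breakpoints
}

#' One-point crossover of two breakpoint sets
#'
#' Children are `c(I1[1:j], I2[(j+1):(k-1)])` and the mirror image, with the
#' cut index j drawn uniformly from `2:(k-2)`. Requires both parents to have
#' the same number of breakpoints, at least 3; otherwise the parents are
#' returned unchanged. Children are re-sorted and repaired to satisfy strict
#' increase and the minimum segment length.
#'
#' @param b1,b2 Parent breakpoint vectors (equal length).
#' @param n_velocity Number of velocity samples.
#' @param min_segment_length Minimum samples per segment.
#' @param j Optional fixed cut index (used mainly for testing); default
#'   drawn uniformly.
#' @return A list of two children.
#' @export
crossover_breakpoints <- function(b1, b2, n_velocity,
                                  min_segment_length = 5L, j = NULL) {
  k1 <- length(b1)
  if (length(b2) != k1 || k1 < 3L) return(list(b1, b2))
  if (is.null(j)) j <- sample(rep(2:(k1 - 1L), 2L), 1L)
  if (j < 2L || j > k1 - 1L) stop("crossover index out of range")
  c1 <- c(b1[1:j], b2[(j + 1L):k1])
  c2 <- c(b2[1:j], b1[(j + 1L):k1])
  list(repair_breakpoints(sort(c1), n_velocity, min_segment_length),
       repair_breakpoints(sort(c2), n_velocity, min_segment_length))
}

# clamp a sorted breakpoint vector to feasibility (gaps >= ml on both ends);
# feasible whenever (k1 + 1) * ml <= n_velocity
repair_breakpoints <- function(bp, n_velocity, ml) {
  k1 <- length(bp)
  prev <- 0
  for (j in seq_len(k1)) {
    if (bp[j] < prev + ml) bp[j] <- prev + ml
    prev <- bp[j]
  }
  nxt <- n_velocity
  for (j in rev(seq_len(k1))) {
    if (bp[j] > nxt - ml) bp[j] <- nxt - ml
    nxt <- bp[j]
  }
  bp
}

# sort each row of a matrix (order() trick: by row, then value)
row_sort <- function(M) {
  matrix(M[order(row(M), M)], nrow = nrow(M), byrow = TRUE)
}

# column-sweep feasibility repair for a whole population matrix
repair_population <- function(P, n_velocity, ml) {
  k1 <- ncol(P)
  prev <- rep(0, nrow(P))
  for (j in seq_len(k1)) {
    P[, j] <- pmax(P[, j], prev + ml)
    prev <- P[, j]
  }
  nxt <- rep(n_velocity, nrow(P))
  for (j in rev(seq_len(k1))) {
    P[, j] <- pmin(P[, j], nxt - ml)
    nxt <- P[, j]
  }
  P
}

# prefix sums of the velocity series for O(k) segment scoring
velocity_prefix <- function(v) {
  list(S1 = rbind(0, apply(v, 2L, cumsum)),
       S2 = c(0, cumsum(v[, 1L]^2 + v[, 2L]^2 + v[, 3L]^2)),
       m = nrow(v))
}

# evaluate every individual of a population: per-segment scores, the
# phase-1 signed sum J1 (first segment positive), and fitness |J1| (the
# objective under the better of the two alternating labellings)
eval_population <- function(P, pre) {
  n <- nrow(P)
  E <- cbind(0L, P, pre$m)
  k <- ncol(E) - 1L
  hi <- as.vector(E[, -1L, drop = FALSE]) + 1L
  lo <- as.vector(E[, -(k + 1L), drop = FALSE]) + 1L
  ns <- as.numeric(hi - lo)
  dx <- pre$S1[hi, 1L] - pre$S1[lo, 1L]
  dy <- pre$S1[hi, 2L] - pre$S1[lo, 2L]
  dz <- pre$S1[hi, 3L] - pre$S1[lo, 3L]
  ss <- pre$S2[hi] - pre$S2[lo] - (dx * dx + dy * dy + dz * dz) / ns
  scores <- matrix(ss / (2 * pi * ns), nrow = n)
  sgn <- rep_len(c(1, -1), k)
  J1 <- drop(scores %*% sgn)
  list(scores = scores, J1 = J1, fitness = abs(J1))
}

#' Tournament-with-royalty generation step
#'
#' The top `ceiling(alpha * beta)` individuals by fitness are copied
#' unchanged (royalty / elitism). The remaining slots are filled by sampling
#' from the non-elite with probability proportional to fitness (shifted to
#' be positive before normalizing, since the objective can be negative),
#' after which one-point crossover is applied to consecutive selected pairs
#' (when the representation allows it) and each offspring receives a +/-1
#' breakpoint mutation with probability `mutation_probability` (infeasible
#' shifts are redrawn a bounded number of times, then dropped).
#'
#' @param population Integer matrix, one breakpoint set per row.
#' @param fitnesses Numeric vector of fitness values, one per row.
#' @param cfg A [ga_config()].
#' @param n_velocity Number of velocity samples being partitioned.
#' @return The next population (same dimensions, elite rows first). With
#'   `royalty_fraction = 1` the population is returned unchanged.
#' @export
next_generation <- function(population, fitnesses, cfg, n_velocity) {
  alpha <- nrow(population)
  k1 <- ncol(population)
  ml <- cfg$min_segment_length
  e <- min(alpha, ceiling(alpha * cfg$royalty_fraction))
  ord <- order(fitnesses, decreasing = TRUE)
  n_off <- alpha - e
  if (n_off == 0L) return(population)
  elite <- population[ord[seq_len(e)], , drop = FALSE]
  pool <- ord[(e + 1L):alpha]
  w <- fitnesses[pool] - min(fitnesses[pool]) + 1e-9
  sel <- pool[sample.int(length(pool), n_off, replace = TRUE, prob = w / sum(w))]
  O <- population[sel, , drop = FALSE]

  if (k1 >= 3L && n_off >= 2L && cfg$crossover_probability > 0) {
    npair <- n_off %/% 2L
    do_cx <- stats::runif(npair) < cfg$crossover_probability
    jcut <- sample(rep(2:(k1 - 1L), 2L), npair, replace = TRUE)
    rows1 <- seq(1L, by = 2L, length.out = npair)
    rows2 <- rows1 + 1L
    colmat <- matrix(seq_len(k1), nrow = npair, ncol = k1, byrow = TRUE)
    swap <- (colmat > jcut) & do_cx
    A <- O[rows1, , drop = FALSE]
    B <- O[rows2, , drop = FALSE]
    O[rows1, ] <- ifelse(swap, B, A)
    O[rows2, ] <- ifelse(swap, A, B)
    O <- repair_population(row_sort(O), n_velocity, ml)
  }

  mut <- stats::runif(n_off) < cfg$mutation_probability
  for (pass in 1:3) {
    if (!any(mut)) break
    jm <- sample.int(k1, n_off, replace = TRUE)
    st <- sample(c(-1, 1), n_off, replace = TRUE)
    idx <- cbind(seq_len(n_off), jm)
    v <- O[idx] + st
    left <- ifelse(jm > 1L, O[cbind(seq_len(n_off), pmax(jm - 1L, 1L))], 0)
    right <- ifelse(jm < k1, O[cbind(seq_len(n_off), pmin(jm + 1L, k1))],
                    n_velocity)
    ok <- mut & (v - left >= ml) & (right - v >= ml)
    if (any(ok)) O[idx[ok, , drop = FALSE]] <- v[ok]
    mut <- mut & !ok
  }
  rbind(elite, O)
}

# uniformly-random feasible population for k segments over m velocity samples
init_population <- function(alpha, k, m, ml) {
  d <- m - k * ml
  U <- matrix(sample.int(d + 1L, alpha * (k - 1L), replace = TRUE) - 1L,
              nrow = alpha)
  U <- row_sort(U)
  U + matrix((seq_len(k - 1L)) * ml, nrow = alpha, ncol = k - 1L, byrow = TRUE)
}

# run the GA for a fixed k on precomputed prefixes; returns best breakpoints,
# fitness and the phase-1 signed sum of the best individual
ga_core <- function(pre, k, cfg) {
  m <- pre$m
  ml <- cfg$min_segment_length
  if (k * ml > m) stop("k = ", k, " is infeasible for ", m,
                       " velocity samples at minimum segment length ", ml)
  P <- init_population(cfg$population_size, k, m, ml)
  ev <- eval_population(P, pre)
  ib <- which.max(ev$fitness)
  best <- list(breakpoints = P[ib, ], fitness = ev$fitness[ib], J1 = ev$J1[ib])
  for (g in seq_len(cfg$generations)) {
    P <- next_generation(P, ev$fitness, cfg, m)
    ev <- eval_population(P, pre)
    ib <- which.max(ev$fitness)
    if (ev$fitness[ib] > best$fitness) {
      best <- list(breakpoints = P[ib, ], fitness = ev$fitness[ib],
                   J1 = ev$J1[ib])
    }
  }
  best
}

build_segmentation <- function(best, k, m, convention, n_samples) {
  start_s <- if (convention == "exploration_positive") best$J1 >= 0
             else best$J1 < 0
  labels <- rep_len(if (start_s) c("s", "o") else c("o", "s"), k)
  bp <- as.integer(best$breakpoints)
  seg_len <- diff(c(0L, bp, m))
  structure(
    list(k = k,
         breakpoints = bp,
         labels = labels,
         objective_value = best$fitness,
         convention = convention,
         sample_labels = rep(labels, times = seg_len),
         offset = 2L,
         n_samples = n_samples),
    class = "ee_segmentation")
}

#' Fit a k-segment alternating segmentation with a genetic algorithm
#'
#' Maximizes the alternating-label objective over all feasible placements of
#' `k - 1` breakpoints using the GA of [next_generation()], starting from a
#' uniformly random feasible population. Both alternating label phases are
#' scored and the better one kept, so the returned labelling is optimal for
#' the returned breakpoints.
#'
#' @param traj Trajectory (see [compute_velocity()]).
#' @param k Number of segments, >= 2.
#' @param cfg A [ga_config()]; `cfg$seed`, when non-NULL, makes the fit
#'   reproducible.
#' @param convention Sign convention, see [objective()].
#' @return An `ee_segmentation`: k, breakpoints (velocity-sample indices),
#'   per-segment labels, `objective_value`, and `sample_labels` expanded over
#'   the stencil-valid samples (trajectory samples `3:(n-2)`).
#' @export
ga_fit <- function(traj, k, cfg = ga_config(),
                   convention = c("exploration_positive",
                                  "exploitation_positive")) {
  convention <- match.arg(convention)
  if (k < 2L) stop("`k` must be at least 2")
  v <- compute_velocity(traj)
  pre <- velocity_prefix(v)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  best <- ga_core(pre, as.integer(k), cfg)
  build_segmentation(best, as.integer(k), pre$m, convention, nrow(v) + 4L)
}

#' Elbow-point choice of the number of segments
#'
#' Given the best objective for each candidate k, returns the k whose point
#' on the objective-vs-k curve lies farthest (perpendicular distance, raw
#' coordinates) from the chord joining the curve's endpoints. Endpoints have
#' zero distance by construction, so only interior k are candidates; ties
#' are broken towards the smallest k. With fewer than 3 points the argmax of
#' the objective is returned.
#'
#' @param objective_by_k Named numeric vector: names are k values, entries
#'   the best objective found for that k.
#' @return The selected k (integer).
#' @export
select_k_elbow <- function(objective_by_k) {
  ks <- as.numeric(names(objective_by_k))
  if (is.null(names(objective_by_k)) || anyNA(ks)) {
    stop("`objective_by_k` must be named by k")
  }
  o <- order(ks)
  ks <- ks[o]
  obj <- as.numeric(objective_by_k)[o]
  np <- length(ks)
  if (np < 3L) return(as.integer(ks[which.max(obj)]))
  x1 <- ks[1L]; y1 <- obj[1L]
  dxv <- ks[np] - x1; dyv <- obj[np] - y1
  len <- sqrt(dxv^2 + dyv^2)
  i <- 2:(np - 1L)
  d <- abs((ks[i] - x1) * dyv - (obj[i] - y1) * dxv)
  if (len > 0) d <- d / len
  as.integer(ks[i][which.max(d)])
}

#' Full exploration--exploitation segmentation pipeline
#'
#' Runs [ga_fit()] for every feasible k from 2 to `cfg$k_max`, applies the
#' elbow rule to the best-objective-per-k curve, and returns the winning
#' segmentation. The objective curve is attached as `objective_by_k`. The
#' output always satisfies the alternation constraint (no two consecutive
#' segments share a label).
#'
#' @param traj Trajectory (see [compute_velocity()]).
#' @param cfg A [ga_config()].
#' @param convention Sign convention, see [objective()].
#' @return An `ee_segmentation` with the elbow-selected k.
#' @export
segment_trajectory <- function(traj, cfg = ga_config(),
                               convention = c("exploration_positive",
                                              "exploitation_positive")) {
  convention <- match.arg(convention)
  v <- compute_velocity(traj)
  pre <- velocity_prefix(v)
  ml <- cfg$min_segment_length
  ks <- 2:cfg$k_max
  ks <- ks[ks * ml <= pre$m]
  if (length(ks) == 0L) {
    stop("trajectory too short to segment at this minimum segment length")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fits <- vector("list", length(ks))
  objs <- numeric(length(ks))
  for (i in seq_along(ks)) {
    fits[[i]] <- ga_core(pre, ks[i], cfg)
    objs[i] <- fits[[i]]$fitness
  }
  names(objs) <- ks
  k_star <- select_k_elbow(objs)
  seg <- build_segmentation(fits[[match(k_star, ks)]], k_star, pre$m,
                            convention, nrow(v) + 4L)
  seg$objective_by_k <- objs
  seg
}

#' Per-sample label agreement between two segmentations
#'
#' The fraction of samples whose predicted exploration/exploitation label
#' equals the ground-truth label. Batch reports average this over flights.
#'
#' @param predicted,truth Character vectors of `"s"`/`"o"` labels of equal
#'   length (restrict both to the stencil-valid sample range first).
#' @return A fraction in \[0, 1\].
#' @export
segmentation_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have the same length")
  }
  if (length(predicted) == 0L) stop("empty label vectors")
  mean(predicted == truth)
}

#' @export
print.ee_segmentation <- function(x, ...) {
  cat("<ee_segmentation> k =", x$k, " objective =",
      format(x$objective_value, digits = 4L), "\n")
  cat("  breakpoints:", paste(x$breakpoints, collapse = ", "), "\n")
  cat("  labels     :", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}
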