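test_that("five-point stencil reproduces its closed forms", {
  # straight line with slope c per sample: every velocity equals -c
  tr <- line_traj(30, slope = c(1, 2, 3))
  v <- compute_velocity(tr)
  expect_equal(nrow(v), 26L)
  expect_true(all(abs(sweep(v, 2L, c(-1, -2, -3))) < 1e-12))
  # constant position: identically zero
  const <- data.frame(t = (0:9) / 75, x = 1, y = 2, z = 3)
  expect_true(all(compute_velocity(const) == 0))
  expect_error(compute_velocity(line_traj(4)), "at least 5")
})

test_that("exploration score matches its closed form and invariances", {
  V <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(exploration_score(V, duration = 2), 1 / (2 * pi))
  # identical velocities: zero dispersion
  expect_equal(exploration_score(rbind(c(2, 1, 0), c(2, 1, 0))), 0)
  # quadratic homogeneity and translation invariance
  set.seed(4)
  W <- matrix(rnorm(60), ncol = 3)
  s0 <- exploration_score(W)
  expect_equal(exploration_score(3 * W), 9 * s0)
  expect_equal(exploration_score(sweep(W, 2L, c(5, -2, 1), "+")), s0)
  expect_error(exploration_score(W[0, , drop = FALSE]), "empty")
})

test_that("objective signs segments by label and validates alternation", {
  set.seed(8)
  tr <- rw_traj(60)
  v <- compute_velocity(tr)
  bp <- 30L
  s1 <- exploration_score(v[1:30, ])
  s2 <- exploration_score(v[31:nrow(v), ])
  seg_so <- list(breakpoints = bp, labels = c("s", "o"))
  expect_equal(objective(tr, seg_so, "exploitation_positive"), -s1 + s2)
  expect_equal(objective(tr, seg_so, "exploration_positive"), s1 - s2)
  # the two conventions are exact negations for fixed labels
  expect_equal(objective(tr, seg_so, "exploration_positive"),
               -objective(tr, seg_so, "exploitation_positive"))
  # k = 1 single segment of identical velocities scores zero
  lin <- line_traj(20)
  expect_equal(objective(lin, list(breakpoints = integer(0), labels = "o")), 0)
  expect_error(objective(tr, list(breakpoints = c(20L, 40L),
                                  labels = c("s", "s", "o"))),
               "alternate")
  # best labelling of a fixed split equals the max over both phases
  both <- c(objective(tr, seg_so),
            objective(tr, list(breakpoints = bp, labels = c("o", "s"))))
  expect_equal(max(both), abs(s1 - s2))
})

test_that("mutation shifts one breakpoint by one and stays feasible", {
  set.seed(5)
  for (rep in 1:200) {
    bp <- c(10L, 20L, 35L)
    out <- mutate_breakpoints(bp, n_velocity = 50L, min_segment_length = 5L)
    d <- out - bp
    expect_true(sum(d != 0) <= 1L)
    expect_true(all(abs(d) <= 1L))
    expect_true(all(diff(c(0L, out, 50L)) >= 5L))
  }
  # boundary: single breakpoint jammed against the minimum index
  jam <- mutate_breakpoints(5L, n_velocity = 10L, min_segment_length = 5L)
  expect_identical(jam, 5L)
  # increments and decrements are balanced
  set.seed(6)
  shifts <- replicate(1e4, {
    out <- mutate_breakpoints(c(50L, 100L), 200L, 5L)
    sum(out - c(50L, 100L))
  })
  p_up <- mean(shifts[shifts != 0] > 0)
  expect_equal(p_up, 0.5, tolerance = 0.03)
})

test_that("crossover implements the one-point exchange", {
  ch <- crossover_breakpoints(c(10L, 20L, 30L, 40L), c(12L, 22L, 32L, 42L),
                              n_velocity = 60L, min_segment_length = 2L,
                              j = 2L)
  expect_equal(ch[[1]], c(10L, 20L, 32L, 42L))
  expect_equal(ch[[2]], c(12L, 22L, 30L, 40L))
  # identical parents reproduce themselves
  same <- crossover_breakpoints(c(10L, 20L, 30L), c(10L, 20L, 30L), 60L, 5L)
  expect_equal(same[[1]], c(10L, 20L, 30L))
  # fewer than 3 breakpoints: parents copied
  skip2 <- crossover_breakpoints(c(10L, 20L), c(15L, 25L), 60L, 5L)
  expect_identical(skip2, list(c(10L, 20L), c(15L, 25L)))
  # children always satisfy the segmentation invariants
  set.seed(9)
  for (rep in 1:100) {
    m <- 80L
    p1 <- sort(sample(5:75, 4L))
    p2 <- sort(sample(5:75, 4L))
    kids <- crossover_breakpoints(p1, p2, m, min_segment_length = 3L)
    for (kid in kids) {
      expect_true(all(diff(c(0L, kid, m)) >= 3L))
    }
  }
})

test_that("royalty selection keeps the elite and tracks fitness", {
  set.seed(10)
  tr <- rw_traj(120)
  v <- compute_velocity(tr)
  pre <- castsurge:::velocity_prefix(v)
  cfg <- ga_config(population_size = 20, royalty_fraction = 0.2,
                   generations = 30, min_segment_length = 5)
  P <- castsurge:::init_population(20L, 4L, pre$m, 5L)
  ev <- castsurge:::eval_population(P, pre)
  # beta = 1 leaves the population untouched
  cfg1 <- ga_config(population_size = 20, royalty_fraction = 1)
  expect_identical(next_generation(P, ev$fitness, cfg1, pre$m), P)
  # elitism: best fitness is monotonically non-decreasing
  best <- max(ev$fitness)
  for (g in 1:30) {
    P <- next_generation(P, ev$fitness, cfg, pre$m)
    ev <- castsurge:::eval_population(P, pre)
    expect_gte(max(ev$fitness) + 1e-15, best)
    best <- max(max(ev$fitness), best)
    # every individual stays feasible
    expect_true(all(apply(cbind(0L, P, pre$m), 1L,
                          function(e) all(diff(e) >= 5L))))
  }
})

test_that("a dominant individual monopolizes fitness-proportional selection", {
  fit <- c(rep(0.001, 19), 100)
  P <- matrix(rep(seq(10, 100, by = 10), each = 20), nrow = 20)
  P[20, ] <- seq(11, 101, by = 10)
  cfg <- ga_config(population_size = 20, royalty_fraction = 0.05,
                   crossover_probability = 0, mutation_probability = 1e-9)
  set.seed(12)
  out <- next_generation(P, fit, cfg, 1000L)
  # the single elite slot keeps the best; among the rest, the dominant
  # individual (after the elite) should fill nearly every slot
  frac_dominant <- mean(apply(out[-1, , drop = FALSE], 1L,
                              function(r) all(r == P[19, ]) ||
                                all(r == P[20, ])))
  expect_gt(frac_dominant, 0.9)
})

test_that("ga_fit recovers a constructed two-regime breakpoint", {
  hits <- 0L
  n_trials <- 20L
  for (i in seq_len(n_trials)) {
    tr <- two_regime_traj(seed = i)
    cfg <- ga_config(population_size = 60, generations = 120,
                     min_segment_length = 40, seed = 1000 + i)
    seg <- ga_fit(tr, k = 2, cfg)
    # construction point: sample 250 -> velocity index 248
    if (abs(seg$breakpoints - 248L) <= 5L) hits <- hits + 1L
    # the noisy half must be the exploration-labelled one
    expect_identical(seg$labels[2], "s")
  }
  expect_gte(hits, round(0.85 * n_trials))
})

test_that("GA matches the exhaustive-search optimum on small instances", {
  matches <- 0L
  n_inst <- 50L
  for (i in seq_len(n_inst)) {
    set.seed(2000 + i)
    n <- sample(40:60, 1L)
    k <- sample(2:3, 1L)
    tr <- rw_traj(n, seed = 2000 + i)
    v <- compute_velocity(tr)
    oracle <- brute_force_best(v, k, min_len = 5L)
    cfg <- ga_config(population_size = 300, generations = 100,
                     mutation_probability = 0.9, seed = 3000 + i)
    seg <- ga_fit(tr, k, cfg)
    if (isTRUE(all.equal(seg$objective_value, oracle$objective,
                         tolerance = 1e-9))) {
      matches <- matches + 1L
    }
  }
  expect_gte(matches, ceiling(0.95 * n_inst))
})

test_that("ga_fit is deterministic given a seed", {
  tr <- rw_traj(150, seed = 3)
  cfg <- ga_config(population_size = 40, generations = 50, seed = 77)
  s1 <- ga_fit(tr, 4, cfg)
  s2 <- ga_fit(tr, 4, cfg)
  expect_identical(s1$breakpoints, s2$breakpoints)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$objective_value, s2$objective_value)
})

test_that("elbow selection follows the chord-distance geometry", {
  # worked example: the bend at k = 3 wins
  curve <- c(`2` = 0, `3` = 9, `4` = 10, `5` = 10.5)
  expect_identical(select_k_elbow(curve), 3L)
  # translation invariance
  expect_identical(select_k_elbow(curve + 100), 3L)
  # perfectly linear curve: no elbow, first interior k by the tie rule
  lin <- stats::setNames(seq(0, 30, length.out = 7), 2:8)
  expect_identical(select_k_elbow(lin), 3L)
  # fewer than 3 points: argmax
  expect_identical(select_k_elbow(c(`2` = 1, `3` = 5)), 3L)
})

test_that("segment_trajectory emits valid alternating segmentations", {
  cfg <- ga_config(population_size = 40, generations = 40, k_max = 8,
                   seed = 5)
  # a rich trajectory and a degenerate straight line both work
  for (tr in list(rw_traj(300, seed = 13), line_traj(200))) {
    seg <- segment_trajectory(tr, cfg)
    k <- seg$k
    expect_gte(k, 2L)
    expect_true(all(seg$labels[-1] != seg$labels[-k]))
    expect_equal(length(seg$sample_labels), nrow(tr) - 4L)
    expect_true(all(diff(c(0L, seg$breakpoints, nrow(tr) - 4L)) >=
                      cfg$min_segment_length))
  }
})

test_that("segmentation recovers the number of simulator mode switches", {
  cfg <- pinned_config()
  ga <- cfg$ga
  hits <- 0L
  trials <- 0L
  set.seed(30)
  sim_seeds <- sample.int(1e6, 80)
  ga_seeds <- sample.int(1e6, 80)
  i <- 0L
  while (trials < 25L && i < 80L) {
    i <- i + 1L
    fl <- simulate_flight(cfg$plume, cfg$wind, cfg$agent, cfg$sensor,
                          seed = sim_seeds[i], warmup = cfg$warmup)
    k_true <- length(fl$switch_indices) + 1L
    if (k_true < 2L || k_true > ga$k_max) next
    seg <- castsurge:::segment_flight(fl, ga, ga_seeds[i])
    if (is.null(seg)) next
    trials <- trials + 1L
    if (abs(seg$k - k_true) <= 2L) hits <- hits + 1L
  }
  expect_gte(trials, 20L)
  expect_gte(hits / trials, 0.5)
})

test_that("per-sample accuracy scores agreement", {
  expect_equal(segmentation_accuracy(c("s", "o"), c("s", "o")), 1)
  expect_equal(segmentation_accuracy(c("s", "o"), c("o", "s")), 0)
  half <- rep(c("s", "o"), 50)
  expect_equal(segmentation_accuracy(half, rep("s", 100)), 0.5)
  expect_error(segmentation_accuracy("s", c("s", "o")), "same length")
})
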