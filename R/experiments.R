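#' Pinned default configuration for the benchmark experiments
#'
#' The published study does not print the simulator's numeric parameters
#' (plume spread and growth, sensor threshold, agent speeds), so the
#' benchmarks in this package run under a single pinned configuration,
#' calibrated once so that the simulated study conditions produce
#' segmentation-accuracy and EER-sweep values in the reported ranges. It is
#' a calibration, not ground truth; see the methods vignette for the
#' rationale behind each value.
#'
#' @return A list with components `plume` ([plume_config()]), `wind`
#'   ([wind_state()]), `agent` ([agent_config()]), `sensor`
#'   ([sensor_config()]), `ga` ([ga_config()]) and `warmup` (seconds of
#'   plume spin-up).
#' @export
pinned_config <- function() {
  list(
    plume = plume_config(),
    wind = wind_state(turbulence_intensity = 0.26),
    agent = agent_config(),
    sensor = sensor_config(),
    ga = ga_config(population_size = 60L, generations = 100L, k_max = 8L,
                   min_segment_length = 25L),
    warmup = 10)
}

#' Simulate a seeded batch of flights
#'
#' Per-flight seeds are derived reproducibly from `seed`, so the whole batch
#' is determined by `(config, seed, n_flights)`.
#'
#' @param n_flights Number of flights.
#' @param seed Master seed for the batch.
#' @param config Configuration list as returned by [pinned_config()].
#' @param overrides Named list of flat config overrides (field names of the
#'   component configs), e.g. `list(puff_frequency = 5)`.
#' @return A list of `flight_record`s.
#' @export
simulate_batch <- function(n_flights, seed = 1L, config = pinned_config(),
                           overrides = list()) {
  config <- apply_overrides(config, overrides)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_flights)
  lapply(seeds, function(s) {
    simulate_flight(config$plume, config$wind, config$agent, config$sensor,
                    seed = s, warmup = config$warmup)
  })
}

# segment one flight record with per-flight GA seed; returns NULL when the
# flight is too short for the stencil + one feasible k
segment_flight <- function(flight, ga_cfg, ga_seed) {
  n <- nrow(flight$trajectory)
  if (n < 4L + 2L * ga_cfg$min_segment_length) return(NULL)
  ga_cfg$seed <- ga_seed
  segment_trajectory(flight$trajectory, ga_cfg)
}

#' Segmentation-accuracy benchmark against simulator ground truth
#'
#' Generates `n_flights` seeded flights under the pinned configuration,
#' recording the simulator's true per-step behavioural modes, runs the full
#' GA segmentation pipeline on each trajectory, and scores the per-sample
#' label agreement. The headline number is the mean accuracy over flights.
#'
#' @param n_flights Number of flights (default 200; the full-scale study
#'   size of 10000 is a matter of patience, not code).
#' @param seed Master seed.
#' @param config Configuration list, default [pinned_config()].
#' @param overrides Flat config overrides, see [simulate_batch()].
#' @return A list with `mean_accuracy`, `sd_accuracy`, `n_flights`,
#'   `success_rate` and a `per_flight` data.frame (seed, n_samples, k_true,
#'   k_fit, accuracy, true_eer, fitted_eer, success).
#' @export
accuracy_benchmark <- function(n_flights = 200L, seed = 1L,
                               config = pinned_config(),
                               overrides = list()) {
  config <- apply_overrides(config, overrides)
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max, n_flights)
  ga_seeds <- sample.int(.Machine$integer.max, n_flights)
  rows <- vector("list", n_flights)
  for (i in seq_len(n_flights)) {
    fl <- simulate_flight(config$plume, config$wind, config$agent,
                          config$sensor, seed = sim_seeds[i],
                          warmup = config$warmup)
    seg <- segment_flight(fl, config$ga, ga_seeds[i])
    n <- nrow(fl$trajectory)
    if (is.null(seg)) next
    truth <- fl$modes[3:(n - 2L)]
    rows[[i]] <- data.frame(
      seed = sim_seeds[i],
      n_samples = n,
      k_true = length(fl$switch_indices) + 1L,
      k_fit = seg$k,
      accuracy = segmentation_accuracy(seg$sample_labels, truth),
      true_eer = mean_eer(truth),
      fitted_eer = mean_eer(seg$sample_labels),
      success = fl$success)
  }
  per_flight <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(mean_accuracy = mean(per_flight$accuracy),
       sd_accuracy = stats::sd(per_flight$accuracy),
       n_flights = nrow(per_flight),
       success_rate = mean(per_flight$success),
       per_flight = per_flight)
}

#' EER sensitivity to the odour-pulse frequency
#'
#' For each release frequency, simulates `n_flights` seeded flights,
#' segments each with the GA pipeline and reports the mean and standard
#' deviation of the per-flight exploration fraction (EER). More frequent
#' odour pockets mean more detections, longer surging and hence lower EER.
#'
#' The source's total emission rate is held constant across the sweep:
#' per-puff strength is scaled as `frequency^-strength_exponent`, so a
#' faster-pulsing source emits the same pheromone mass per unit time rather
#' than `frequency` times more. Set `strength_exponent = 0` for fixed
#' per-puff strength.
#'
#' @param frequencies Release frequencies in puffs per second.
#' @param n_flights Flights per frequency (default 100).
#' @param seed Master seed.
#' @param config Configuration list.
#' @param overrides Flat config overrides applied on top.
#' @param strength_exponent Exponent of the per-puff strength scaling
#'   (default 0.6, the pinned calibration).
#' @return A data.frame with columns `frequency`, `mean_eer`, `sd_eer`,
#'   `mean_true_eer`, `n_flights`.
#' @export
frequency_sweep <- function(frequencies = c(1, 3, 5, 7, 9),
                            n_flights = 100L, seed = 1L,
                            config = pinned_config(),
                            overrides = list(),
                            strength_exponent = 0.6) {
  config <- apply_overrides(config, overrides)
  base_q <- config$plume$puff_strength
  out <- vector("list", length(frequencies))
  for (fi in seq_along(frequencies)) {
    cfg <- apply_overrides(config, list(
      puff_frequency = frequencies[fi],
      puff_strength = base_q * frequencies[fi]^(-strength_exponent)))
    set.seed(seed + fi - 1L)
    sim_seeds <- sample.int(.Machine$integer.max, n_flights)
    ga_seeds <- sample.int(.Machine$integer.max, n_flights)
    eer <- true_eer <- rep(NA_real_, n_flights)
    for (i in seq_len(n_flights)) {
      fl <- simulate_flight(cfg$plume, cfg$wind, cfg$agent, cfg$sensor,
                            seed = sim_seeds[i], warmup = cfg$warmup)
      seg <- segment_flight(fl, cfg$ga, ga_seeds[i])
      if (is.null(seg)) next
      n <- nrow(fl$trajectory)
      eer[i] <- mean_eer(seg$sample_labels)
      true_eer[i] <- mean_eer(fl$modes[3:(n - 2L)])
    }
    out[[fi]] <- data.frame(frequency = frequencies[fi],
                            mean_eer = mean(eer, na.rm = TRUE),
                            sd_eer = stats::sd(eer, na.rm = TRUE),
                            mean_true_eer = mean(true_eer, na.rm = TRUE),
                            n_flights = sum(!is.na(eer)))
  }
  do.call(rbind, out)
}

#' Undisturbed vs disturbed flow comparison
#'
#' Runs matched seeded batches at two turbulence intensities and compares
#' the EER-vs-distance curves, the per-flight mean EER distributions and the
#' success rates. In disturbed flow the plume is more dispersed, detections
#' are rarer and more erratic near the source, and the agent explores more.
#'
#' @param intensities Two turbulence intensities, default `c(0.05, 0.3)`
#'   (undisturbed vs disturbed).
#' @param n_flights Flights per intensity.
#' @param seed Master seed (the same per-flight seeds are used at both
#'   intensities, so the comparison is paired).
#' @param config Configuration list.
#' @param label_source `"truth"` (default) uses the simulator's ground-truth
#'   modes — the cleanest statement of how the *behaviour* depends on
#'   turbulence, free of estimation error; `"segmentation"` labels each
#'   flight with the GA pipeline instead, as one must with measured flights.
#' @param band_radius Distance-band half-width, metres.
#' @return A list with per-intensity `curves` (class `eer_curve`),
#'   `per_flight_eer`, `success_rate`, and `mean_eer`.
#' @export
turbulence_comparison <- function(intensities = c(0.05, 0.3),
                                  n_flights = 60L, seed = 1L,
                                  config = pinned_config(),
                                  label_source = c("truth", "segmentation"),
                                  band_radius = 0.06) {
  label_source <- match.arg(label_source)
  stopifnot(length(intensities) >= 2L)
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max, n_flights)
  ga_seeds <- sample.int(.Machine$integer.max, n_flights)
  res <- list()
  for (ti in intensities) {
    cfg <- apply_overrides(config, list(turbulence_intensity = ti))
    labelled <- list()
    eers <- rep(NA_real_, n_flights)
    succ <- logical(n_flights)
    for (i in seq_len(n_flights)) {
      fl <- simulate_flight(cfg$plume, cfg$wind, cfg$agent, cfg$sensor,
                            seed = sim_seeds[i], warmup = cfg$warmup)
      succ[i] <- fl$success
      n <- nrow(fl$trajectory)
      if (label_source == "segmentation") {
        seg <- segment_flight(fl, cfg$ga, ga_seeds[i])
        if (is.null(seg)) next
        df <- fl$trajectory[3:(n - 2L), c("x", "y", "z")]
        df$mode <- seg$sample_labels
      } else {
        df <- fl$trajectory[, c("x", "y", "z")]
        df$mode <- fl$modes
      }
      labelled[[length(labelled) + 1L]] <- df
      eers[i] <- mean_eer(df$mode)
    }
    key <- format(ti)
    res[[key]] <- list(
      intensity = ti,
      curve = eer_vs_distance(labelled,
                              target = cfg$plume$source_position,
                              band_radius = band_radius),
      per_flight_eer = eers[!is.na(eers)],
      success_rate = mean(succ),
      mean_eer = mean(eers, na.rm = TRUE))
  }
  res
}

#' Simulator-vs-observed fit quality report
#'
#' For each observed trajectory, runs `n_runs` seeded simulations, takes the
#' [mean_path()] as the model path, and scores it against the observation
#' with [dtw_mae()] and [path_r2()]. The report repeats this under four
#' simulator configurations -- baseline (instant manoeuvring, noiseless
#' sensing), bounded acceleration only, input noise only, and both -- so the
#' contribution of each modification is visible.
#'
#' @param observed A trajectory (data.frame / `flight_record` / CSV path) or
#'   a list of them.
#' @param n_runs Simulator runs averaged into each model path.
#' @param seed Master seed.
#' @param config Configuration list.
#' @return A list with `report` (one row per configuration: mean and s.d. of
#'   DTW-MAE and of clamped R2, plus raw R2) and `per_path` (per observed
#'   path values).
#' @export
fit_quality <- function(observed, n_runs = 100L, seed = 1L,
                        config = pinned_config()) {
  if (!is.list(observed) || is.data.frame(observed) ||
      inherits(observed, "flight_record")) {
    observed <- list(observed)
  }
  observed <- lapply(observed, function(o) {
    if (is.character(o)) {
      if (!file.exists(o)) stop("missing trajectory file: ", o)
      o <- read_trajectory_csv(o)
    }
    o
  })
  combos <- data.frame(
    configuration = c("baseline", "bounded_acceleration", "noisy_input",
                      "bounded_acceleration+noisy_input"),
    bounded = c(FALSE, TRUE, FALSE, TRUE),
    noisy = c(FALSE, FALSE, TRUE, TRUE))
  base_acc <- config$agent$max_acceleration
  base_frac <- config$sensor$noise_sigma_fraction
  per_path <- list()
  report <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    ov <- list(
      max_acceleration = if (combos$bounded[ci]) base_acc else Inf,
      noise_sigma_fraction = if (combos$noisy[ci]) base_frac else 0)
    cfg <- apply_overrides(config, ov)
    flights <- simulate_batch(n_runs, seed = seed, config = cfg)
    model <- mean_path(flights)
    mae <- r2c <- r2raw <- numeric(length(observed))
    for (oi in seq_along(observed)) {
      mae[oi] <- as.numeric(dtw_mae(observed[[oi]], model))
      r2 <- path_r2(observed[[oi]], model, clamp = TRUE)
      r2c[oi] <- as.numeric(r2)
      r2raw[oi] <- attr(r2, "raw")
    }
    per_path[[combos$configuration[ci]]] <-
      data.frame(path = seq_along(observed), mae = mae, r2 = r2c,
                 r2_raw = r2raw)
    report[[ci]] <- data.frame(
      configuration = combos$configuration[ci],
      mae_mean = mean(mae), mae_sd = stats::sd(mae),
      r2_mean = mean(r2c), r2_sd = stats::sd(r2c),
      r2_raw_mean = mean(r2raw))
  }
  list(report = do.call(rbind, report), per_path = per_path)
}
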