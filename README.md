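# castsurge

Moth-inspired olfactory navigation, simulated and decoded.

Male moths find calling females by alternating two behaviours inside a
wind-borne pheromone plume: **exploitation** (`o` — surging upwind after a
recent odour detection) and **exploration** (`s` — casting crosswind after
losing the signal). `castsurge` is an R package for studying this
exploration–exploitation (EE) decomposition computationally. It provides:

* a **3D puff-based plume simulator** — discrete Gaussian odour pockets
  released from a point source, advected by a mean wind plus
  Ornstein–Uhlenbeck fluctuations, dispersed by per-puff turbulent jitter,
  growing by diffusion;
* a **memoryless cast-and-surge agent** — binary thresholded odour sensing
  and local wind sensing, both with Gaussian noise scaled to 2% of the
  running-average input; a surge timer as the only internal state; bounded
  acceleration and speed; ground-truth behavioural labels logged at every
  step;
* an **EE segmentation method** for bare trajectories: five-point-stencil
  velocities, a per-segment velocity-dispersion score
  `o(p) = (1/2π) Σ ‖v_i − v̄‖² / (t_e − t_s)`, an alternating-label
  objective maximized by a genetic algorithm (±1 breakpoint mutation,
  one-point crossover, tournament-with-royalty selection) with elbow-point
  selection of the number of segments k;
* **trajectory metrics** — dynamic time warping with mean-absolute-error
  cost, path R², mean paths over seeded batches, and EER-vs-distance
  curves with a 0.06 m error radius;
* **benchmark experiments** — segmentation accuracy against simulator
  ground truth, EER sensitivity to the odour-pocket release frequency
  (1–9 per second), disturbed vs undisturbed flow comparison, and a
  four-configuration fit-quality report for measured flights.

Trajectories are plain data frames (`t, x, y, z`, 75 Hz by default), so
measured flights can be read from CSV with `read_trajectory_csv()` and fed
to the same segmentation and metrics functions.

## Worked example

Simulate one flight under the pinned benchmark configuration, recover its
exploration/exploitation phases from the trajectory alone, and compare with
the simulator's ground truth:

```r
library(castsurge)

cfg <- pinned_config()
flight <- simulate_flight(cfg$plume, cfg$wind, cfg$agent, cfg$sensor,
                          seed = 42, warmup = cfg$warmup)
flight
#> <flight_record> 1501 samples ( 20.00 s ), 2 mode switches, no success

ga <- cfg$ga; ga$seed <- 42L
seg <- segment_trajectory(flight$trajectory, ga)
seg
#> <ee_segmentation> k = 3  objective = 2.124e-05
#>   breakpoints: 870, 999
#>   labels     : s o s

n <- nrow(flight$trajectory)
segmentation_accuracy(seg$sample_labels, flight$modes[3:(n - 2)])
#> [1] 0.927
mean_eer(seg$sample_labels)   # fitted exploration fraction
#> [1] 0.914
mean_eer(flight$modes)        # ground truth
#> [1] 0.841
```

This flight cast for most of its 20 s (it never reached the source), with
one surge bout between samples ~872 and ~1001; the segmentation recovers
that structure from the kinematics alone with 92.7% per-sample agreement,
and its exploration fraction (EER) overestimates the true one by 0.07 —
see the methods vignette for why the fitted EER is biased upward on
surge-heavy stretches.

Batch experiments follow the same pattern:

```r
accuracy_benchmark(n_flights = 200, seed = 1)   # mean label accuracy
frequency_sweep(n_flights = 100, seed = 1)      # EER vs pocket frequency
turbulence_comparison(n_flights = 50, seed = 1) # disturbed vs undisturbed
```

A thin command-line front end with the same capabilities ships in
`inst/cli/castsurge` (subcommands `simulate`, `segment`,
`accuracy-benchmark`, `frequency-sweep`, `turbulence-compare`,
`fit-quality`).

## Documentation

The methods vignette (`vignettes/castsurge-methods.Rmd`) describes the
plume and agent models and their assumptions, the segmentation objective
and its sign convention, the GA operators, every tunable parameter with
units and defaults, the calibration behind the pinned configuration, and
known limitations — including the upward bias of fitted EER on
exploitation-dominated flights, which is a property of the published
segmentation objective rather than of the optimizer.
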