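Package: castsurge
Title: Cast-and-Surge Olfactory Navigation Simulation and
    Exploration-Exploitation Trajectory Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates moth-like olfactory navigation in three dimensions: a
    Gaussian-puff pheromone plume released from a point source into a
    fluctuating wind, and a memoryless cast-and-surge agent with binary
    thresholded odour sensing, noisy local wind sensing, a surge timer and
    bounded acceleration. Flight trajectories (simulated or measured) are
    segmented into alternating exploration (casting) and exploitation
    (surging) phases by maximizing a velocity-dispersion objective with a
    genetic algorithm and elbow-point model selection. Includes trajectory
    comparison metrics (dynamic time warping with mean-absolute-error cost,
    coefficient of determination), exploration-exploitation rate (EER)
    analytics as a function of distance from the odour source, and
    benchmark experiments for segmentation accuracy, odour-pulse-frequency
    sensitivity and turbulence-intensity comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
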