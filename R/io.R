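#' Read a trajectory CSV
#'
#' Expects columns `t, x, y, z` (seconds and metres) and optionally a label
#' column `mode` with `"s"`/`"o"` entries.
#'
#' @param path File path.
#' @return A data.frame trajectory.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns t, x, y, z")
  }
  df
}

#' Write a flight record (or plain trajectory) to CSV
#'
#' Columns `t, x, y, z` plus `mode` when per-sample labels are available.
#'
#' @param flight A `flight_record` or a trajectory data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flight_csv <- function(flight, path) {
  if (inherits(flight, "flight_record")) {
    df <- flight$trajectory
    df$mode <- flight$modes
  } else {
    df <- flight
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a batch manifest as JSON
#'
#' Records seeds, success flags and the shared configuration of a batch of
#' simulated flights, so a batch is fully reconstructable.
#'
#' @param flights List of `flight_record`s.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_batch_manifest <- function(flights, path) {
  cfg <- flights[[1L]]$configs
  manifest <- list(
    n_flights = length(flights),
    seeds = vapply(flights, function(f) f$seed, numeric(1)),
    success = vapply(flights, function(f) f$success, logical(1)),
    config = lapply(cfg, unclass))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a segmentation to JSON
#'
#' @param seg An `ee_segmentation`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_segmentation_json <- function(seg, path) {
  jsonlite::write_json(
    list(k = seg$k,
         breakpoints = seg$breakpoints,
         labels = seg$labels,
         objective = seg$objective_value,
         convention = seg$convention,
         offset = seg$offset),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a flat configuration file (YAML or JSON)
#'
#' Keys are matched by name against the fields of [plume_config()],
#' [wind_state()], [agent_config()], [sensor_config()] and [ga_config()];
#' unknown keys raise an error. Returns the pinned default configuration
#' with the file's overrides applied.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file with flat keys.
#' @param base Base configuration to override, default [pinned_config()].
#' @return A configuration list like [pinned_config()]'s.
#' @export
read_config <- function(path, base = pinned_config()) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  apply_overrides(base, raw)
}

# route flat key/value overrides to the component configs by field name
apply_overrides <- function(config, overrides) {
  if (length(overrides) == 0L) return(config)
  for (key in names(overrides)) {
    hit <- FALSE
    for (part in names(config)) {
      if (key %in% names(config[[part]])) {
        val <- overrides[[key]]
        if (is.list(val)) val <- unlist(val)
        config[[part]][[key]] <- val
        hit <- TRUE
      }
    }
    if (!hit) stop("unknown configuration key: ", key)
  }
  # re-validate through the constructors
  config$plume <- do.call(plume_config, unclass(config$plume))
  config$wind <- do.call(wind_state, unclass(config$wind))
  config$agent <- do.call(agent_config, unclass(config$agent))
  config$sensor <- do.call(sensor_config, unclass(config$sensor))
  config$ga <- do.call(ga_config, unclass(config$ga))
  config
}
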