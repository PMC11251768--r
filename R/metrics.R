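#' Dynamic time warping distance with mean-absolute-error cost
#'
#' Classic DTW over two 3D point sequences. The local cost of matching point
#' i of `path_a` to point j of `path_b` is the mean absolute coordinate
#' difference; the alignment minimizing the cumulative cost is found by
#' dynamic programming (anti-diagonal vectorized), and the total cost is
#' divided by the warping-path length so values are comparable across path
#' lengths. The unnormalized total and the path length are attached as
#' attributes.
#'
#' Symmetric, non-negative, zero exactly when the paths are identical up to
#' repeated points.
#'
#' @param path_a,path_b Trajectories (data.frames with x, y, z, matrices or
#'   `flight_record`s); both non-empty.
#' @param normalize Divide the total cost by the warping-path length
#'   (default TRUE).
#' @return Scalar alignment cost with attributes `total_cost` and
#'   `path_length`.
#' @export
dtw_mae <- function(path_a, path_b, normalize = TRUE) {
  A <- as_position_matrix(path_a)
  B <- as_position_matrix(path_b)
  n <- nrow(A)
  m <- nrow(B)
  if (n == 0L || m == 0L) stop("paths must be non-empty")
  C <- (abs(outer(A[, 1L], B[, 1L], "-")) +
        abs(outer(A[, 2L], B[, 2L], "-")) +
        abs(outer(A[, 3L], B[, 3L], "-"))) / 3

  D <- matrix(Inf, n, m)
  L <- matrix(0L, n, m)
  D[1L, 1L] <- C[1L, 1L]
  L[1L, 1L] <- 1L
  # sweep anti-diagonals d = i + j; cells on a diagonal are independent
  for (d in seq(3L, length.out = max(0L, n + m - 2L))) {
    i <- max(1L, d - m):min(n, d - 1L)
    j <- d - i
    keep <- !(i == 1L & j == 1L)
    i <- i[keep]; j <- j[keep]
    if (length(i) == 0L) next
    idx <- (j - 1L) * n + i
    up <- left <- diag <- rep(Inf, length(idx))
    oi <- i > 1L
    oj <- j > 1L
    up[oi] <- D[idx[oi] - 1L]
    left[oj] <- D[idx[oj] - n]
    diag[oi & oj] <- D[idx[oi & oj] - n - 1L]
    best <- pmin(diag, up, left)
    prev_len <- rep(0L, length(idx))
    pick_left <- left <= best
    pick_up <- up <= best
    pick_diag <- diag <= best
    prev_len[pick_left] <- L[idx[pick_left] - n]
    prev_len[pick_up] <- L[idx[pick_up] - 1L]
    prev_len[pick_diag] <- L[idx[pick_diag] - n - 1L]
    D[idx] <- C[idx] + best
    L[idx] <- prev_len + 1L
  }
  total <- D[n, m]
  plen <- L[n, m]
  out <- if (normalize) total / plen else total
  attr(out, "total_cost") <- total
  attr(out, "path_length") <- plen
  out
}

#' Coefficient of determination between two paths
#'
#' `1 - SS_res / SS_tot`, pooled over the three coordinates, after linearly
#' resampling the model path to the observed path's length on normalized
#' time. `SS_tot` uses the observed path's per-coordinate means. The raw
#' value can be negative when the model explains less than the observed
#' mean; `clamp = TRUE` reports `max(0, R2)` (the raw value is attached as
#' attribute `raw`).
#'
#' @param observed,model Trajectories (data.frames, matrices or
#'   `flight_record`s).
#' @param clamp Report `max(0, R2)` instead of the raw value.
#' @return Scalar R-squared (<= 1).
#' @export
path_r2 <- function(observed, model, clamp = FALSE) {
  Y <- as_position_matrix(observed)
  M <- as_position_matrix(model)
  n <- nrow(Y)
  if (n < 2L) stop("observed path must have at least 2 samples")
  if (nrow(M) != n) M <- resample_positions(M, n)
  mu <- colMeans(Y)
  ss_tot <- sum(sweep(Y, 2L, mu)^2)
  if (ss_tot == 0) stop("observed path has zero variance in every coordinate")
  ss_res <- sum((Y - M)^2)
  r2 <- 1 - ss_res / ss_tot
  out <- if (clamp) max(0, r2) else r2
  attr(out, "raw") <- r2
  out
}

resample_positions <- function(M, n_out) {
  n <- nrow(M)
  if (n == 1L) return(matrix(M, nrow = n_out, ncol = 3L, byrow = TRUE))
  u <- seq(0, 1, length.out = n)
  uo <- seq(0, 1, length.out = n_out)
  cbind(stats::approx(u, M[, 1L], xout = uo)$y,
        stats::approx(u, M[, 2L], xout = uo)$y,
        stats::approx(u, M[, 3L], xout = uo)$y)
}

#' Mean exploration--exploitation rate of a label sequence
#'
#' The EER of a stretch of flight is the fraction of samples labelled as
#' exploration (`"s"`); 1 means pure casting, 0 pure surging.
#'
#' @param labels Non-empty character vector of `"s"`/`"o"` labels.
#' @return A fraction in \[0, 1\].
#' @export
mean_eer <- function(labels) {
  if (length(labels) == 0L) stop("`labels` must be non-empty")
  mean(labels == "s")
}

#' Exploration--exploitation rate as a function of distance from the target
#'
#' Samples from all flights are assigned to non-overlapping distance bands
#' of half-width `band_radius` (the "error radius") centred on a regular
#' grid from `band_radius` to `max_distance`. Within each band, the
#' exploration fraction is computed per flight and its mean and standard
#' deviation are reported across flights (`mode = "per_flight"`, the
#' default), or the pooled fraction over all samples with a binomial-style
#' s.d. (`mode = "pooled"`). Bands no flight visits are reported as `NA`
#' (empty), not zero.
#'
#' @param flights List of labelled flights: `flight_record`s (ground-truth
#'   labels) or data.frames with columns x, y, z and a label column `mode`.
#' @param target Target position (length 3), default the plume source of the
#'   first flight record if available.
#' @param band_radius Band half-width in metres (default 0.06).
#' @param max_distance Largest band centre, metres (default 2, the release
#'   distance).
#' @param mode Aggregation mode, see above.
#' @return A data.frame of class `eer_curve` with columns `band_centre`,
#'   `mean_eer`, `sd_eer`, `n_samples`, `n_flights`.
#' @export
eer_vs_distance <- function(flights, target = NULL, band_radius = 0.06,
                            max_distance = 2,
                            mode = c("per_flight", "pooled")) {
  mode <- match.arg(mode)
  if (length(flights) == 0L) stop("need at least one flight")
  if (band_radius <= 0) stop("`band_radius` must be positive")
  if (is.null(target)) {
    f1 <- flights[[1L]]
    if (inherits(f1, "flight_record")) {
      target <- f1$configs$plume$source_position
    } else {
      stop("`target` must be given when flights are plain data.frames")
    }
  }
  centres <- seq(band_radius, max_distance, by = 2 * band_radius)
  nb <- length(centres)
  per_flight <- matrix(NA_real_, nrow = length(flights), ncol = nb)
  counts <- matrix(0L, nrow = length(flights), ncol = nb)
  s_counts <- matrix(0L, nrow = length(flights), ncol = nb)
  for (fi in seq_along(flights)) {
    f <- flights[[fi]]
    if (inherits(f, "flight_record")) {
      pos <- as_position_matrix(f$trajectory)
      lab <- f$modes
    } else {
      pos <- as_position_matrix(f)
      if (is.null(f$mode)) stop("data.frame flights need a `mode` column")
      lab <- f$mode
    }
    d <- sqrt((pos[, 1L] - target[1L])^2 + (pos[, 2L] - target[2L])^2 +
              (pos[, 3L] - target[3L])^2)
    band <- floor(d / (2 * band_radius)) + 1L
    inside <- band >= 1L & band <= nb
    band <- band[inside]
    is_s <- lab[inside] == "s"
    if (length(band) > 0L) {
      counts[fi, ] <- tabulate(band, nbins = nb)
      s_counts[fi, ] <- tabulate(band[is_s], nbins = nb)
      nz <- counts[fi, ] > 0L
      per_flight[fi, nz] <- s_counts[fi, nz] / counts[fi, nz]
    }
  }
  n_samples <- colSums(counts)
  n_flights <- colSums(counts > 0L)
  if (mode == "per_flight") {
    mean_e <- colMeans(per_flight, na.rm = TRUE)
    sd_e <- apply(per_flight, 2L, stats::sd, na.rm = TRUE)
  } else {
    mean_e <- colSums(s_counts) / n_samples
    sd_e <- sqrt(pmax(mean_e * (1 - mean_e), 0) / pmax(n_samples, 1L))
  }
  mean_e[n_samples == 0L] <- NA_real_
  sd_e[n_samples == 0L] <- NA_real_
  out <- data.frame(band_centre = centres,
                    mean_eer = mean_e,
                    sd_eer = sd_e,
                    n_samples = n_samples,
                    n_flights = n_flights)
  class(out) <- c("eer_curve", "data.frame")
  out
}

#' @export
plot.eer_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  ok <- !is.na(x$mean_eer)
  if (!add) {
    plot(x$band_centre[ok], x$mean_eer[ok], type = "l", col = col,
         xlab = "distance from target (m)", ylab = "EER",
         ylim = c(0, 1), ...)
  } else {
    graphics::lines(x$band_centre[ok], x$mean_eer[ok], col = col, ...)
  }
  sdl <- x$mean_eer[ok] - x$sd_eer[ok]
  sdh <- x$mean_eer[ok] + x$sd_eer[ok]
  graphics::lines(x$band_centre[ok], pmax(sdl, 0), lty = 3L, col = col)
  graphics::lines(x$band_centre[ok], pmin(sdh, 1), lty = 3L, col = col)
  invisible(x)
}
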