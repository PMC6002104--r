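#' Kernel density estimate of one population snapshot
#'
#' Gaussian kernel smoothing of the individual positions,
#' \deqn{\rho(x) = \frac{1}{N h} \sum_{i=1}^N K\!\left(\frac{x - x_i}{h}\right),}
#' with `K` the standard normal density and `h` the smoothing bandwidth
#' (default 0.1). The displacement `x - x_i` is taken as the minimal-image
#' displacement on the ring, so the estimate is periodic and free of seam
#' artifacts; with `h` much smaller than `L` this is indistinguishable from
#' the line version away from the boundary. The estimate integrates to 1
#' over the ring (up to quadrature error).
#'
#' @param positions numeric vector of N coordinates in `[0, L)`.
#' @param grid spatial evaluation points in `[0, L)`.
#' @param h bandwidth (space units), `> 0`. Default 0.1.
#' @param L ring length.
#' @return Numeric vector of density values at `grid`.
#' @export
kde_density <- function(positions, grid, h = 0.1, L) {
  if (length(positions) == 0L) stop("'positions' must be non-empty")
  stopifnot(is.numeric(h), h > 0, is.numeric(L), L > 0)
  dx <- outer(grid, positions, function(g, p) signed_displacement(p, g, L))
  rowMeans(stats::dnorm(dx / h)) / h
}

#' Space-time density field of a trajectory
#'
#' Applies [kde_density()] to every recorded frame.
#'
#' @param trajectory a `swarm_trajectory`.
#' @param grid spatial evaluation points in `[0, L)`; default 500 equally
#'   spaced points.
#' @param h bandwidth, default 0.1.
#' @return An object of class `density_field`: list with `grid`, `times`,
#'   `values` (times x grid matrix), `bandwidth`.
#' @export
spacetime_density <- function(trajectory, grid = NULL, h = 0.1) {
  stopifnot(inherits(trajectory, "swarm_trajectory"))
  L <- trajectory$config$L
  if (is.null(grid)) grid <- seq(0, L, length.out = 501)[-501]
  values <- t(apply(trajectory$positions, 1L, kde_density,
                    grid = grid, h = h, L = L))
  if (length(grid) == 1L) values <- matrix(values, ncol = 1L)
  structure(list(grid = grid, times = trajectory$times, values = values,
                 bandwidth = h, L = L),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf(
    "density_field: %d frames x %d grid points, bandwidth %g, max %g\n",
    nrow(x$values), length(x$grid), x$bandwidth, max(x$values)))
  invisible(x)
}

#' Normalize a density field to unit maximum
#'
#' Divides all values by the global space-time maximum so the brightest
#' point of the raster is exactly 1 (the colour scaling used for density
#' heat maps). Idempotent.
#'
#' @param field a `density_field`.
#' @return The rescaled `density_field`.
#' @export
normalize_max <- function(field) {
  stopifnot(inherits(field, "density_field"))
  m <- max(field$values)
  if (!is.finite(m) || m <= 0) stop("field has no positive values")
  field$values <- field$values / m
  field
}

#' Heat-map plot of a density field
#'
#' @param x a `density_field`.
#' @param ... passed to [graphics::image()].
#' @export
plot.density_field <- function(x, ...) {
  graphics::image(x$times, x$grid, x$values, xlab = "time",
                  ylab = "position", useRaster = TRUE, ...)
  invisible(x)
}

#' Write a density field to CSV
#'
#' Plain-matrix export: one row per recorded time, one column per grid
#' point; the first column holds the time stamp.
#'
#' @param field a `density_field`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_density_field <- function(field, path) {
  df <- data.frame(time = field$times, field$values)
  names(df) <- c("time", sprintf("x_%g", field$grid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# circular mean of ring positions, in [0, L)
circular_mean <- function(x, L) {
  theta <- 2 * pi * x / L
  (atan2(mean(sin(theta)), mean(cos(theta))) %% (2 * pi)) * L / (2 * pi)
}

# angular deviation sqrt(2 (1 - R)) mapped back to space units; bounded by
# sqrt(2) L / (2 pi) < L / 2
circular_sd <- function(x, L) {
  theta <- 2 * pi * x / L
  R <- sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
  sqrt(2 * (1 - R)) * L / (2 * pi)
}

#' Order-parameter diagnostics of a trajectory
#'
#' Scalar summaries per recorded frame, used to characterise the
#' space-time patterns quantitatively:
#' \describe{
#'   \item{polarization}{`|mean heading|`, 0 (balanced) to 1 (all moving
#'     one way).}
#'   \item{centroid}{circular mean position of the population, in
#'     `[0, L)`.}
#'   \item{drift_speed}{signed rate of change of the unwrapped centroid
#'     over a trailing window of `window` time units (`NA` for frames
#'     earlier than one window).}
#'   \item{aggregation_width}{circular standard deviation (angular
#'     deviation) of the positions, in space units, bounded by
#'     `sqrt(2) L / (2 pi)`.}
#' }
#'
#' @param trajectory a `swarm_trajectory`.
#' @param window width of the drift-speed window in time units; must span
#'   at least 2 recorded frames. Default 20 frame intervals.
#' @return A data frame of class `pattern_diagnostics` with columns
#'   `time`, `polarization`, `centroid`, `drift_speed`,
#'   `aggregation_width`.
#' @export
diagnostics <- function(trajectory, window = NULL) {
  stopifnot(inherits(trajectory, "swarm_trajectory"))
  L <- trajectory$config$L
  times <- trajectory$times
  n_frames <- length(times)
  if (n_frames < 1L) stop("trajectory is empty")
  frame_dt <- if (n_frames > 1L) times[2L] - times[1L] else NA_real_
  if (is.null(window)) window <- 20 * frame_dt
  pol <- abs(rowMeans(trajectory$directions))
  cen <- apply(trajectory$positions, 1L, circular_mean, L = L)
  wid <- apply(trajectory$positions, 1L, circular_sd, L = L)
  # unwrap the centroid across ring crossings
  unwrapped <- cen
  if (n_frames > 1L) {
    jumps <- diff(cen)
    jumps[jumps > L / 2] <- jumps[jumps > L / 2] - L
    jumps[jumps < -L / 2] <- jumps[jumps < -L / 2] + L
    unwrapped <- cen[1L] + c(0, cumsum(jumps))
  }
  drift <- rep(NA_real_, n_frames)
  if (n_frames > 1L) {
    lag <- max(1L, round(window / frame_dt))
    if (lag >= n_frames) lag <- n_frames - 1L
    idx <- (lag + 1L):n_frames
    drift[idx] <- (unwrapped[idx] - unwrapped[idx - lag]) /
      (times[idx] - times[idx - lag])
  }
  structure(data.frame(time = times, polarization = pol, centroid = cen,
                       drift_speed = drift, aggregation_width = wid),
            class = c("pattern_diagnostics", "data.frame"))
}

#' Width of the dominant density peak per frame
#'
#' For each frame, the spatial width (in space units, ring wrap included)
#' of the widest contiguous region whose density exceeds
#' `threshold * max(frame)`. Unlike a global dispersion measure, this
#' tracks the expansion and contraction of an aggregation even when
#' several groups coexist on the ring, which makes it the natural
#' breathing diagnostic.
#'
#' @param field a `density_field`.
#' @param threshold relative threshold in (0, 1), default 0.5.
#' @return Numeric vector, one width per frame.
#' @export
dominant_peak_width <- function(field, threshold = 0.5) {
  stopifnot(inherits(field, "density_field"),
            threshold > 0, threshold < 1)
  cell <- field$L / length(field$grid)
  widths <- apply(field$values, 1L, function(row) {
    above <- row > threshold * max(row)
    if (all(above)) return(length(row))
    shift <- which(!above)[1L]
    above <- c(above[shift:length(above)], above[seq_len(shift - 1L)])
    r <- rle(above)
    max(r$lengths[r$values])
  })
  unname(widths) * cell
}

#' Propagation speed of a space-time density pattern
#'
#' Estimates the signed speed at which the density pattern translates by
#' circular cross-correlation: for every pair of frames `lag_frames`
#' apart, the later frame is circularly shifted until it best matches the
#' earlier one, and the mean best shift per unit time (averaged over all
#' such pairs, via the summed FFT cross-correlation) is returned.
#' Stationary patterns give a speed near zero; a rigidly traveling
#' pattern gives its translation velocity, even when counter-moving
#' individuals hold the population polarization near zero.
#'
#' @param field a `density_field` with at least `lag_frames + 1` frames.
#' @param lag_frames frame separation used for the correlation, default 5.
#' @return Signed speed (space/time); positive means rightward motion.
#' @export
pattern_speed <- function(field, lag_frames = 5L) {
  stopifnot(inherits(field, "density_field"))
  nf <- nrow(field$values)
  ng <- ncol(field$values)
  if (nf < lag_frames + 1L) stop("too few frames for this lag")
  A <- t(field$values[seq_len(nf - lag_frames), , drop = FALSE])
  B <- t(field$values[(lag_frames + 1L):nf, , drop = FALSE])
  # summed circular cross-correlation over all frame pairs
  cc <- rowSums(Re(stats::mvfft(stats::mvfft(B) * Conj(stats::mvfft(A)),
                                inverse = TRUE)))
  s <- which.max(cc) - 1L            # grid cells the pattern moved
  if (s > ng / 2) s <- s - ng        # signed minimal shift
  cell <- field$L / ng
  dt_lag <- (field$times[1L + lag_frames] - field$times[1L])
  s * cell / dt_lag
}

#' Mean local polarization of a population snapshot
#'
#' For each individual, the mean heading of all conspecifics within
#' `radius` (itself included) is computed; the statistic is the average of
#' the absolute local means. It measures whether individuals travel with
#' locally aligned neighbours — near `1/sqrt(n_local)` for a disordered
#' population, and well above it when coherent bands exist, even when
#' left- and right-moving bands coexist and cancel in the global
#' polarization.
#'
#' @param state a [population_state].
#' @param radius neighbourhood radius (space units), default 0.5 (the
#'   default alignment-zone centre).
#' @return A scalar in `[0, 1]`.
#' @export
local_polarization <- function(state, radius = 0.5) {
  stopifnot(inherits(state, "population_state"), radius > 0)
  x <- state$positions
  v <- state$directions
  D <- outer(x, x, function(a, b) signed_displacement(a, b, state$L))
  near <- abs(D) <= radius
  mean(abs((near %*% v) / rowSums(near)))
}

#' Space-time density of one heading subpopulation
#'
#' Kernel density field ([spacetime_density()]) restricted to the
#' individuals moving in one direction. Each frame is normalized by the
#' subpopulation size of that frame. The translation speed of this field
#' ([pattern_speed()]) tracks band motion even when counter-moving bands
#' make the full-population field appear static.
#'
#' @param trajectory a `swarm_trajectory`.
#' @param direction `+1` (right-movers) or `-1` (left-movers).
#' @param grid spatial evaluation points; default 500 equally spaced.
#' @param h bandwidth, default 0.1.
#' @return A `density_field` (frames with no individuals of the chosen
#'   heading give a zero row).
#' @export
direction_density <- function(trajectory, direction = 1, grid = NULL,
                              h = 0.1) {
  stopifnot(inherits(trajectory, "swarm_trajectory"),
            direction %in% c(-1, 1))
  L <- trajectory$config$L
  if (is.null(grid)) grid <- seq(0, L, length.out = 501)[-501]
  values <- t(vapply(seq_len(nrow(trajectory$positions)), function(k) {
    sel <- trajectory$directions[k, ] == direction
    if (!any(sel)) return(numeric(length(grid)))
    kde_density(trajectory$positions[k, sel], grid, h, L)
  }, numeric(length(grid))))
  structure(list(grid = grid, times = trajectory$times, values = values,
                 bandwidth = h, L = L),
            class = "density_field")
}

#' Count density peaks above a relative threshold
#'
#' For each frame of a density field, counts the contiguous runs of grid
#' points (with ring wrap-around) whose density exceeds
#' `threshold * max(frame)`. Used to track fission-fusion dynamics: the
#' peak count rises when a group splits and falls when groups merge.
#'
#' @param field a `density_field`.
#' @param threshold relative threshold in (0, 1), default 0.5.
#' @return Integer vector, one count per frame.
#' @export
count_density_peaks <- function(field, threshold = 0.5) {
  stopifnot(inherits(field, "density_field"),
            threshold > 0, threshold < 1)
  counts <- apply(field$values, 1L, function(row) {
    above <- row > threshold * max(row)
    if (all(above)) return(1L)
    # rotate so the first grid point is below threshold: runs never wrap
    shift <- which(!above)[1L]
    above <- c(above[shift:length(above)], above[seq_len(shift - 1L)])
    sum(diff(c(FALSE, above)) == 1L)
  })
  unname(counts)
}
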