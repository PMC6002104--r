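#' Draw a random initial population state
#'
#' Positions are i.i.d. uniform on `[0, L)`; headings are i.i.d. +1/-1 with
#' probability 1/2 each. Consumes exactly `2 * n` uniform draws from the
#' current RNG stream (`n` for positions, then `n` for headings), so runs
#' are reproducible across implementations that respect this draw order.
#'
#' @param config a `swarm_config`.
#' @return A [population_state] at time 0.
#' @export
init_state <- function(config) {
  x <- stats::runif(config$n, 0, config$L)
  x[x >= config$L] <- 0  # guard against runif returning the upper bound
  v <- ifelse(stats::runif(config$n) < 0.5, 1L, -1L)
  population_state(x, v, config$L, time = 0)
}

#' Advance one step with constant speed
#'
#' Synchronous update: (1) turning rates are computed for every individual
#' from the current state; (2) every individual moves distance
#' `gamma * dt` in its heading, wrapped onto `[0, L)`; (3) each heading
#' flips iff `lambda_i * dt >= X_i`, with one fresh uniform draw `X_i` per
#' individual (in index order). All three substeps use only the pre-step
#' state, so the order of (2) and (3) is immaterial.
#'
#' @param state a [population_state].
#' @param config a `swarm_config` with `speed_mode = "constant"`.
#' @return The next [population_state].
#' @export
step_constant_speed <- function(state, config) {
  fs <- compute_forces(state, config)
  lam <- turning_rate(fs$y_r, fs$y_al, fs$y_a, config_turning_params(config))
  x_new <- (state$positions + config$gamma * state$directions * config$dt) %%
    config$L
  u <- stats::runif(length(state$positions))
  flip <- lam * config$dt >= u
  v_new <- ifelse(flip, -state$directions, state$directions)
  population_state(x_new, v_new, config$L, time = state$time + config$dt)
}

#' Advance one step with density-dependent speed
#'
#' Synchronous update for the density-dependent-speed variant:
#' (1) alignment-only turning rates from the current state;
#' (2) headings flip iff `lambda_i * dt >= X_i` (one uniform per
#' individual, index order); (3) social forces are recomputed with the NEW
#' headings at the pre-move positions, so individuals do not respond to
#' stale signals; (4) each individual moves distance
#' `Gamma_i * dt` in its new heading, where
#' `Gamma_i = gamma * (1 + tanh(y_a - y_r))` uses the recomputed forces.
#'
#' @inheritParams step_constant_speed
#' @return The next [population_state].
#' @export
step_density_dependent <- function(state, config) {
  fs <- compute_forces(state, config)
  lam <- turning_rate_alignment_only(fs$y_al, config_turning_params(config),
                                     apply_alpha = config$apply_alpha_dds)
  u <- stats::runif(length(state$positions))
  flip <- lam * config$dt >= u
  v_new <- as.integer(ifelse(flip, -state$directions, state$directions))
  mid <- population_state(state$positions, v_new, config$L,
                          time = state$time)
  fs2 <- compute_forces(mid, config)
  speed <- density_dependent_speed(fs2$y_a, fs2$y_r, config$gamma)
  x_new <- (state$positions + speed * v_new * config$dt) %% config$L
  population_state(x_new, v_new, config$L, time = state$time + config$dt)
}

#' Run a full simulation
#'
#' Seeds the RNG from `config$seed` (if non-`NULL`), draws the initial
#' state (unless `init` is supplied), then iterates the stepper matching
#' `config$speed_mode` for `config$horizon` steps, recording every
#' `config$record_every`-th frame (the initial state is always frame 1).
#' Identical seed and config give a bit-identical trajectory.
#'
#' @param config a `swarm_config`.
#' @param init optional [population_state] to start from instead of a
#'   random initial condition (no initialisation draws are consumed).
#' @param engine `"cpp"` (compiled inner loop, default) or `"r"` (pure-R
#'   reference stepper). Both follow the same RNG draw discipline: one
#'   uniform per individual per step, in index order.
#' @return An object of class `swarm_trajectory`: list with `times`
#'   (recorded time stamps), `positions` and `directions`
#'   (frames x n matrices) and `config`.
#' @export
run_simulation <- function(config, init = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  validate_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- if (is.null(init)) init_state(config) else init
  stopifnot(inherits(state, "population_state"),
            length(state$positions) == config$n)
  if (engine == "cpp") {
    res <- run_engine_cpp(
      state$positions, as.integer(state$directions),
      n_steps = config$horizon, record_every = config$record_every,
      L = config$L, dt = config$dt, gamma = config$gamma,
      lambda1 = config$lambda1, lambda2 = config$lambda2,
      y0 = config$y0, alpha = config$alpha,
      q_r = config$q_r, q_al = config$q_al, q_a = config$q_a,
      kr = unlist(config$kernels$r[c("centre", "width", "cutoff")]),
      kal = unlist(config$kernels$al[c("centre", "width", "cutoff")]),
      ka = unlist(config$kernels$a[c("centre", "width", "cutoff")]),
      submodel = as.integer(sub("M", "", config$submodel)),
      density_dependent = config$speed_mode == "density_dependent",
      apply_alpha_dds = config$apply_alpha_dds,
      t0 = state$time)
    traj <- list(times = res$times, positions = res$positions,
                 directions = res$directions, config = config)
  } else {
    stepper <- switch(config$speed_mode,
                      constant = step_constant_speed,
                      density_dependent = step_density_dependent)
    n_frames <- config$horizon %/% config$record_every + 1L
    pos <- matrix(NA_real_, n_frames, config$n)
    dir <- matrix(NA_integer_, n_frames, config$n)
    times <- numeric(n_frames)
    pos[1L, ] <- state$positions
    dir[1L, ] <- state$directions
    times[1L] <- state$time
    frame <- 1L
    if (config$horizon >= 1L) {
      for (step in seq_len(config$horizon)) {
        state <- stepper(state, config)
        if (step %% config$record_every == 0L) {
          frame <- frame + 1L
          pos[frame, ] <- state$positions
          dir[frame, ] <- state$directions
          times[frame] <- state$time
        }
      }
    }
    traj <- list(times = times, positions = pos, directions = dir,
                 config = config)
  }
  structure(traj, class = "swarm_trajectory")
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  cat(sprintf(
    "swarm_trajectory: %d frames x %d individuals, t in [%g, %g]\n",
    nrow(x$positions), ncol(x$positions), x$times[1],
    x$times[length(x$times)]))
  invisible(x)
}

#' Extract one recorded frame as a population state
#'
#' @param trajectory a `swarm_trajectory`.
#' @param frame frame index (1 = initial state).
#' @return A [population_state].
#' @export
trajectory_frame <- function(trajectory, frame) {
  stopifnot(inherits(trajectory, "swarm_trajectory"),
            frame >= 1L, frame <= nrow(trajectory$positions))
  population_state(trajectory$positions[frame, ],
                   trajectory$directions[frame, ],
                   trajectory$config$L, time = trajectory$times[frame])
}

#' Tidy data frame view of a trajectory
#'
#' @param x a `swarm_trajectory`.
#' @param ... unused.
#' @return A data frame with columns `time`, `individual_id`, `position`,
#'   `direction` (long format, one row per individual per recorded frame).
#' @export
as.data.frame.swarm_trajectory <- function(x, ...) {
  n_frames <- nrow(x$positions)
  n <- ncol(x$positions)
  data.frame(time = rep(x$times, times = n),
             individual_id = rep(seq_len(n), each = n_frames),
             position = as.vector(x$positions),
             direction = as.vector(x$directions))
}

#' Write a trajectory to CSV
#'
#' Long-format export with columns `time`, `individual_id`, `position`,
#' `direction`.
#'
#' @param trajectory a `swarm_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
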