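#' Simulation configuration
#'
#' Collects every model constant needed for a run. The social-stimulus
#' scaling defaults to `alpha = A * L / N` where `A` is the total mass of
#' the population (default 2): force sums over individuals are rescaled by
#' the reciprocal of the number density `N / L`, then by `A`, so the same
#' turning-rate parameters apply at any population size.
#'
#' @param n number of individuals, `>= 1`. Default 500.
#' @param L ring length (space units), `> 0`. Default 10.
#' @param dt time step, `> 0`. Default 0.05.
#' @param horizon number of steps to simulate, `>= 0`. Default 20000
#'   (1000 time units at the default `dt`).
#' @param record_every record a frame every this many steps, `>= 1`.
#'   Default 20.
#' @param lambda1,lambda2 baseline and bias turning rates (1/time).
#'   Defaults 0.2 and 0.9.
#' @param y0 turning-function shift, default 2.
#' @param alpha social-stimulus scaling; if `NULL` (default), computed as
#'   `total_mass * L / n`.
#' @param total_mass total population mass `A` used to construct `alpha`.
#'   Default 2.
#' @param gamma baseline movement speed (space/time), `> 0`. Default 0.1.
#' @param speed_mode `"constant"` or `"density_dependent"`.
#' @param q_r,q_al,q_a magnitudes of the repulsion, alignment and
#'   attraction forces, `>= 0`.
#' @param submodel direction-dependent interaction rule, one of
#'   `"M1"` ... `"M5"`.
#' @param kernel_variant `"original"` or `"revised_repulsion"`; used to
#'   build `kernels` when they are not supplied.
#' @param kernels optional list of three [kernel_params] (`r`, `al`, `a`);
#'   default [default_kernels()] with `kernel_variant`.
#' @param apply_alpha_dds logical; apply `alpha` inside the alignment-only
#'   turning rate of the density-dependent-speed model. Default `FALSE`
#'   (the stimulus is used unscaled, as printed).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `swarm_config` (a validated named list).
#' @export
simulation_config <- function(n = 500, L = 10, dt = 0.05, horizon = 20000,
                              record_every = 20,
                              lambda1 = 0.2, lambda2 = 0.9, y0 = 2,
                              alpha = NULL, total_mass = 2,
                              gamma = 0.1,
                              speed_mode = c("constant", "density_dependent"),
                              q_r = 0, q_al = 0, q_a = 0,
                              submodel = "M1",
                              kernel_variant = c("original",
                                                 "revised_repulsion"),
                              kernels = NULL,
                              apply_alpha_dds = FALSE,
                              seed = NULL) {
  speed_mode <- match.arg(speed_mode)
  kernel_variant <- match.arg(kernel_variant)
  if (is.null(alpha)) alpha <- total_mass * L / n
  if (is.null(kernels)) kernels <- default_kernels(variant = kernel_variant)
  cfg <- structure(list(
    n = as.integer(n), L = L, dt = dt, horizon = as.integer(horizon),
    record_every = as.integer(record_every),
    lambda1 = lambda1, lambda2 = lambda2, y0 = y0,
    alpha = alpha, total_mass = total_mass,
    gamma = gamma, speed_mode = speed_mode,
    q_r = q_r, q_al = q_al, q_a = q_a,
    submodel = submodel, kernel_variant = kernel_variant,
    kernels = kernels, apply_alpha_dds = isTRUE(apply_alpha_dds),
    seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "swarm_config")
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks all field constraints and errors with a message naming the first
#' offending field. Called by [simulation_config()] and [read_config()].
#'
#' @param config a `swarm_config` object (or bare list with its fields).
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop(sprintf("invalid config: '%s' %s", field, what),
                          call. = FALSE)
  }
  num1 <- function(z) is.numeric(z) && length(z) == 1L && is.finite(z)
  chk(num1(config$n) && config$n >= 1, "n", "must be >= 1")
  chk(num1(config$L) && config$L > 0, "L", "must be > 0")
  chk(num1(config$dt) && config$dt > 0, "dt", "must be > 0")
  chk(num1(config$horizon) && config$horizon >= 0, "horizon",
      "must be >= 0")
  chk(num1(config$record_every) && config$record_every >= 1,
      "record_every", "must be >= 1")
  chk(num1(config$lambda1) && config$lambda1 >= 0, "lambda1",
      "must be >= 0")
  chk(num1(config$lambda2) && config$lambda2 >= 0, "lambda2",
      "must be >= 0")
  chk(num1(config$y0), "y0", "must be a finite number")
  chk(num1(config$alpha) && config$alpha > 0, "alpha", "must be > 0")
  chk(num1(config$gamma) && config$gamma > 0, "gamma", "must be > 0")
  chk(num1(config$q_r) && config$q_r >= 0, "q_r", "must be >= 0")
  chk(num1(config$q_al) && config$q_al >= 0, "q_al", "must be >= 0")
  chk(num1(config$q_a) && config$q_a >= 0, "q_a", "must be >= 0")
  chk(config$submodel %in% paste0("M", 1:5), "submodel",
      "must be one of M1..M5")
  chk(config$speed_mode %in% c("constant", "density_dependent"),
      "speed_mode", "must be 'constant' or 'density_dependent'")
  chk(is.list(config$kernels) &&
        all(c("r", "al", "a") %in% names(config$kernels)) &&
        all(vapply(config$kernels[c("r", "al", "a")],
                   inherits, logical(1), "kernel_params")),
      "kernels", "must hold kernel_params 'r', 'al', 'a'")
  invisible(config)
}

#' @export
print.swarm_config <- function(x, ...) {
  cat(sprintf(
    paste0("swarm_config: N = %d on [0, %g), dt = %g, %d steps, %s\n",
           "  submodel %s (%s kernels), q = (%g, %g, %g), ",
           "lambda = (%g, %g), alpha = %g, gamma = %g\n"),
    x$n, x$L, x$dt, x$horizon, x$speed_mode,
    x$submodel, x$kernel_variant, x$q_r, x$q_al, x$q_a,
    x$lambda1, x$lambda2, x$alpha, x$gamma))
  invisible(x)
}

# turning_params view of a config
config_turning_params <- function(config) {
  turning_params(config$lambda1, config$lambda2, config$alpha, config$y0)
}
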