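# Named parameterisations known to produce each space-time pattern.
# Shared constants across all presets: N = 500, L = 10, A = 2, dt = 0.05,
# gamma = 0.1; constant-speed rows use the zonal kernel set, the dds_*
# rows use density-dependent speed with alignment-only turning.
preset_table <- function() {
  rows <- list(
    #                      submodel lambda1 lambda2  q_r q_al  q_a  speed
    stationary_pulse_1   = list("M1", 0.2,  0.9, 2.4, 0,   2,   "constant"),
    stationary_pulse_2   = list("M2", 0.2,  0.9, 0.5, 0,   4,   "constant"),
    ripples              = list("M5", 0.2,  0.9, 1.1, 2,   1.5, "constant"),
    feathers             = list("M3", 0.2,  0.9, 6.4, 0,   6,   "constant"),
    traveling_pulse      = list("M1", 0.2,  0.9, 0.5, 2,   1.6, "constant"),
    traveling_train      = list("M3", 6.67, 30,  0,   2,   6,   "constant"),
    # reconstruction of the traveling-train regime: the reference row's
    # turning rates factor as 0.2/0.03 and 0.9/0.03, i.e. the
    # alignment-only sweep at alpha = 0.03, where the original q_a = 6
    # saturates the turning function under rule M3 (ahead-only sums) and
    # freezes all turning bias; with alignment only, trains form
    traveling_train_alignment_only =
                           list("M3", 6.67, 30,  0,   2,   0,   "constant",
                                alpha = 0.03),
    zigzag_pulse         = list("M2", 0.2,  0.9, 1,   2,   6,   "constant"),
    breathers            = list("M4", 0.2,  0.9, 1,   0,   2,   "constant"),
    traveling_breathers  = list("M4", 0.2,  0.9, 4,   2,   4,   "constant"),
    dds_stationary_pulse_a = list("M1", 0.2, 0.9, 0.1, 0,   0.5,
                                  "density_dependent"),
    dds_stationary_pulse_b = list("M1", 0.2, 0.9, 0.1, 2,   0.7,
                                  "density_dependent"),
    dds_splitting_merging_alignment = list("M1", 0.2, 0.9, 0.1, 3.5, 0.2,
                                           "density_dependent"),
    dds_splitting_merging_no_alignment = list("M1", 0.2, 0.9, 0.5, 0, 0.1,
                                              "density_dependent"))
  rows
}

#' Names of the built-in pattern presets
#'
#' Nine reference constant-speed presets (one per documented pattern),
#' one reconstruction (`traveling_train_alignment_only`, see
#' [load_preset()]), and four density-dependent-speed presets
#' (stationary pulses with and without alignment; splitting-and-merging
#' with and without alignment).
#'
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(preset_table())

#' Load a named pattern preset
#'
#' Builds the full simulation configuration for one of the built-in
#' pattern-forming parameterisations. All presets share N = 500, L = 10,
#' total mass A = 2 (so `alpha = A * L / N = 0.04`), `dt = 0.05`,
#' `gamma = 0.1`, a 20000-step horizon recorded every 20 steps, and the
#' default kernel set. The one exception is
#' `"traveling_train_alignment_only"`, this package's reconstruction of
#' the traveling-train regime: it keeps the reference turning rates
#' (which factor as `0.2 / 0.03` and `0.9 / 0.03`, identifying the
#' alignment-only sweep at `alpha = 0.03`) but drops attraction, whose
#' reference magnitude saturates the turning function under the
#' ahead-only rule M3 and freezes every turning bias (see the methods
#' vignette).
#'
#' @param name preset name; see [preset_names()].
#' @param ... overrides passed on to [simulation_config()] (e.g. `seed`,
#'   `horizon`, `kernel_variant`).
#' @return A `swarm_config`.
#' @examples
#' cfg <- load_preset("breathers", seed = 1, horizon = 2000)
#' @export
load_preset <- function(name, ...) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(names(tab), collapse = ", ")))
  row <- tab[[name]]
  defaults <- list(n = 500, L = 10, dt = 0.05, total_mass = 2, gamma = 0.1,
                   horizon = 20000, record_every = 20,
                   submodel = row[[1]], lambda1 = row[[2]],
                   lambda2 = row[[3]], q_r = row[[4]], q_al = row[[5]],
                   q_a = row[[6]], speed_mode = row[[7]])
  if (!is.null(row$alpha)) defaults$alpha <- row$alpha
  overrides <- list(...)
  do.call(simulation_config, utils::modifyList(defaults, overrides))
}

#' Parameter-sweep specification
#'
#' The three canonical sweep regimes:
#' \describe{
#'   \item{case "a"}{repulsion and attraction only: `q_al = 0`,
#'     `lambda1 = 0.2`, `lambda2 = 0.9`; `q_r` and `q_a` varied over
#'     `[0.5, 9]`.}
#'   \item{case "b"}{alignment only: `q_r = q_a = 0`; `alpha` varied over
#'     `[0.006, 1]` and `q_al` over `[0.5, 10]`, with the turning rates
#'     tied to `alpha` via `rate_scaling` (`"divide"`:
#'     `lambda1 = 0.2 / alpha`, `lambda2 = 0.9 / alpha`; `"multiply"`:
#'     `0.2 * alpha`, `0.9 * alpha`).}
#'   \item{case "c"}{all social interactions: `lambda1 = 0.2`,
#'     `lambda2 = 0.9`; `q_r`, `q_al`, `q_a` varied over `[1, 10]`.}
#' }
#'
#' @param case `"a"`, `"b"` or `"c"`.
#' @param n_grid grid points per varied axis, default 8.
#' @param submodels character vector of interaction rules to cross with
#'   the grid; default all of M1..M5.
#' @param seeds integer vector of replicate seeds, default 1.
#' @param rate_scaling for case "b" only: how the turning rates scale
#'   with `alpha`; default `"divide"`.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(case = c("a", "b", "c"), n_grid = 8,
                       submodels = paste0("M", 1:5), seeds = 1L,
                       rate_scaling = c("divide", "multiply")) {
  case <- match.arg(case)
  rate_scaling <- match.arg(rate_scaling)
  stopifnot(n_grid >= 1, length(submodels) >= 1,
            all(submodels %in% paste0("M", 1:5)), length(seeds) >= 1)
  structure(list(case = case, n_grid = as.integer(n_grid),
                 submodels = submodels, seeds = as.integer(seeds),
                 rate_scaling = rate_scaling),
            class = "sweep_spec")
}

#' Enumerate the configurations of a parameter sweep
#'
#' Deterministic enumeration of the Cartesian product grid x submodels x
#' seeds for the given [sweep_spec()]; varied axes are equally spaced
#' grids over the case's ranges, enumerated with the first axis varying
#' fastest, then later axes, then submodel, then seed. Every emitted
#' configuration passes [validate_config()].
#'
#' @param spec a `sweep_spec`.
#' @param ... shared overrides passed to [simulation_config()]
#'   (e.g. `horizon`, `n`).
#' @return A list of `swarm_config` objects.
#' @export
sweep_configs <- function(spec, ...) {
  stopifnot(inherits(spec, "sweep_spec"))
  g <- function(lo, hi) {
    if (spec$n_grid == 1L) (lo + hi) / 2
    else seq(lo, hi, length.out = spec$n_grid)
  }
  grid <- switch(spec$case,
    a = expand.grid(q_r = g(0.5, 9), q_a = g(0.5, 9)),
    b = expand.grid(alpha = g(0.006, 1), q_al = g(0.5, 10)),
    c = expand.grid(q_r = g(1, 10), q_al = g(1, 10), q_a = g(1, 10)))
  out <- vector("list", nrow(grid) * length(spec$submodels) *
                  length(spec$seeds))
  k <- 0L
  for (seed in spec$seeds) {
    for (sm in spec$submodels) {
      for (r in seq_len(nrow(grid))) {
        args <- list(submodel = sm, seed = seed, ...)
        if (spec$case == "a") {
          args <- c(args, list(q_r = grid$q_r[r], q_a = grid$q_a[r],
                               q_al = 0, lambda1 = 0.2, lambda2 = 0.9))
        } else if (spec$case == "b") {
          a <- grid$alpha[r]
          lam <- if (spec$rate_scaling == "divide") c(0.2 / a, 0.9 / a)
                 else c(0.2 * a, 0.9 * a)
          args <- c(args, list(q_r = 0, q_a = 0, q_al = grid$q_al[r],
                               alpha = a, lambda1 = lam[1],
                               lambda2 = lam[2]))
        } else {
          args <- c(args, list(q_r = grid$q_r[r], q_al = grid$q_al[r],
                               q_a = grid$q_a[r], lambda1 = 0.2,
                               lambda2 = 0.9))
        }
        k <- k + 1L
        out[[k]] <- do.call(simulation_config, args)
      }
    }
  }
  out
}

# configuration file schema -------------------------------------------------

config_file_keys <- c("n", "L", "dt", "horizon", "record_every", "lambda1",
                      "lambda2", "y0", "alpha", "total_mass", "gamma",
                      "speed_mode", "q_r", "q_al", "q_a", "submodel",
                      "kernel_variant", "kernels", "apply_alpha_dds",
                      "seed")

#' Write a configuration to a YAML file
#'
#' The file is a flat YAML mapping of the [simulation_config()] fields,
#' with the three kernels as a nested mapping of `centre`/`width`/`cutoff`
#' triples. [read_config()] reproduces an identical configuration.
#'
#' @param config a `swarm_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  x$kernels <- lapply(x$kernels,
                      function(k) k[c("centre", "width", "cutoff")])
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected with a message naming them; missing optional
#' keys fall back to the [simulation_config()] defaults (in particular,
#' a file giving `total_mass`, `L` and `n` but no `alpha` gets
#' `alpha = total_mass * L / n`). The result is validated before being
#' returned.
#'
#' @param path YAML file path.
#' @return A `swarm_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.list(x) || is.null(names(x)))
    stop("config file must be a YAML mapping")
  unknown <- setdiff(names(x), config_file_keys)
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
  if (!is.null(x$kernels)) {
    need <- c("r", "al", "a")
    if (!all(need %in% names(x$kernels)))
      stop("'kernels' must name entries 'r', 'al', 'a'")
    x$kernels <- lapply(x$kernels[need], function(k)
      kernel_params(k$centre, k$width, k$cutoff))
  }
  do.call(simulation_config, x)
}
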