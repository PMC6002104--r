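#' Logistic turning function
#'
#' The bounded, increasing function that converts a net social stimulus into
#' a turning bias:
#' \deqn{f(x) = \frac{1}{1 + e^{-2(x - y_0)}} = \frac{1}{2} + \frac{\tanh(x - y_0)}{2}.}
#' With the default shift `y0 = 2`, `f(0)` is close to zero, so an
#' individual receiving no social stimulus turns at essentially its baseline
#' rate.
#'
#' @param x net social stimulus (dimensionless). Vectorised.
#' @param y0 shift of the logistic (dimensionless), default 2.
#' @return Value(s) strictly inside (0, 1).
#' @export
turning_function <- function(x, y0 = 2) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric")
  0.5 + 0.5 * tanh(x - y0)
}

#' Turning-rate parameters
#'
#' @param lambda1 baseline turning rate (1/time), `>= 0`.
#' @param lambda2 bias turning rate (1/time), `>= 0`.
#' @param alpha dimensionless scaling of the social stimulus, `> 0`. For a
#'   population of `N` individuals on a ring of length `L` with total mass
#'   `A`, the conventional choice is `alpha = A * L / N`, which converts
#'   per-capita force sums onto the density scale.
#' @param y0 shift of the turning function, default 2.
#' @return An object of class `turning_params`.
#' @export
turning_params <- function(lambda1, lambda2, alpha = 1, y0 = 2) {
  stopifnot(is.numeric(lambda1), is.numeric(lambda2), is.numeric(alpha),
            is.numeric(y0), lambda1 >= 0, lambda2 >= 0, alpha > 0,
            is.finite(lambda1), is.finite(lambda2), is.finite(alpha),
            is.finite(y0))
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 alpha = alpha, y0 = y0),
            class = "turning_params")
}

#' Turning rate from the three social forces
#'
#' \deqn{\lambda = \lambda_1 + \lambda_2 f(\alpha (y_r - y_a + y_{al}))}
#' Repulsion and alignment increase the turning rate; attraction enters with
#' the opposite sign because it has the opposite biological effect (an
#' individual should keep moving toward an attractive group, not turn away
#' from it). The rate is strictly between `lambda1` and
#' `lambda1 + lambda2` for finite forces.
#'
#' @param y_r,y_al,y_a signed repulsion, alignment, attraction forces for
#'   the individual's own heading. Vectorised.
#' @param params a [turning_params] object.
#' @return Turning rate(s) (1/time).
#' @export
turning_rate <- function(y_r, y_al, y_a, params) {
  stopifnot(inherits(params, "turning_params"))
  stim <- params$alpha * (y_r - y_a + y_al)
  params$lambda1 + params$lambda2 * turning_function(stim, params$y0)
}

#' Alignment-only turning rate (density-dependent-speed variant)
#'
#' In the density-dependent-speed model individuals change direction only in
#' response to alignment:
#' \deqn{\lambda = \lambda_1 + \lambda_2 f(y_{al}).}
#' The stimulus is used as printed, without the `alpha` scaling of
#' [turning_rate()]; set `apply_alpha = TRUE` to scale for consistency
#' experiments.
#'
#' @param y_al signed alignment force for the individual's own heading.
#' @param params a [turning_params] object.
#' @param apply_alpha logical; multiply the stimulus by `params$alpha`
#'   before applying the turning function. Default `FALSE`.
#' @return Turning rate(s) (1/time).
#' @export
turning_rate_alignment_only <- function(y_al, params, apply_alpha = FALSE) {
  stopifnot(inherits(params, "turning_params"))
  stim <- if (apply_alpha) params$alpha * y_al else y_al
  params$lambda1 + params$lambda2 * turning_function(stim, params$y0)
}

#' Density-dependent movement speed
#'
#' Individuals speed up to join distant groups and slow down to avoid
#' collisions by comparing attraction and repulsion:
#' \deqn{\Gamma = \gamma (1 + \tanh(y_a - y_r)),}
#' strictly increasing in `y_a - y_r` and bounded in `(0, 2 * gamma)`. At
#' zero net stimulus the speed is exactly the baseline `gamma`.
#'
#' @param y_a,y_r signed attraction and repulsion forces for the
#'   individual's own heading. Vectorised.
#' @param gamma baseline speed (space/time), `> 0`. Default 0.1.
#' @return Speed(s) (space/time) in `(0, 2 * gamma)`.
#' @export
density_dependent_speed <- function(y_a, y_r, gamma = 0.1) {
  stopifnot(is.numeric(gamma), gamma > 0, is.finite(gamma))
  if (any(!is.finite(y_a)) || any(!is.finite(y_r)))
    stop("forces must be finite")
  gamma * (1 + tanh(y_a - y_r))
}
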