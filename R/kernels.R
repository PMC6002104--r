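#' Interaction kernel parameters
#'
#' An interaction zone (repulsion, alignment or attraction) weights
#' neighbours by a truncated Gaussian of the pairwise distance. `centre` is
#' the distance at which the weight peaks, `width` the Gaussian standard
#' deviation, and `cutoff` the truncation radius beyond which the weight is
#' exactly zero. The default zonal organisation places the repulsion,
#' alignment and attraction peaks at 0.25, 0.5 and 1 space units with widths
#' one eighth of the centre and cutoffs at twice the centre.
#'
#' @param centre peak distance of the kernel (space units), `>= 0`.
#' @param width Gaussian standard deviation (space units), `> 0`.
#' @param cutoff truncation radius (space units), `> 0`. Defaults to
#'   `2 * centre` (and to `2 * width` when `centre == 0`, so a centred
#'   kernel still has finite support).
#' @return An object of class `kernel_params`: a list with elements
#'   `centre`, `width`, `cutoff`.
#' @examples
#' kp <- kernel_params(centre = 0.25, width = 0.03125)
#' kernel_weight(0.25, kp) # Gaussian peak height, ~12.77
#' @export
kernel_params <- function(centre, width, cutoff = NULL) {
  stopifnot(is.numeric(centre), length(centre) == 1L, is.finite(centre),
            is.numeric(width), length(width) == 1L, is.finite(width))
  if (centre < 0) stop("'centre' must be >= 0")
  if (width <= 0) stop("'width' must be > 0")
  if (is.null(cutoff)) cutoff <- if (centre > 0) 2 * centre else 2 * width
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  if (cutoff <= 0) stop("'cutoff' must be > 0")
  structure(list(centre = centre, width = width, cutoff = cutoff),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("Gaussian interaction kernel: centre %g, width %g, cutoff %g\n",
              x$centre, x$width, x$cutoff))
  invisible(x)
}

#' Evaluate a truncated Gaussian interaction kernel
#'
#' Computes the zone weight
#' \deqn{K(d) = \frac{1}{\sqrt{2\pi m^2}} \exp\left(-\frac{(d - s)^2}{2 m^2}\right)}
#' for distance `d`, peak distance `s = params$centre` and width
#' `m = params$width`, truncated to exactly zero for `d > params$cutoff`.
#' A distance exactly at the cutoff is inside the support.
#'
#' @param distance non-negative distance(s) between two individuals
#'   (space units). Vectorised.
#' @param params a [kernel_params] object.
#' @return Non-negative weight(s), units 1/space.
#' @export
kernel_weight <- function(distance, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (!is.numeric(distance) || any(!is.finite(distance)))
    stop("'distance' must be finite numeric")
  if (any(distance < 0)) stop("'distance' must be >= 0")
  m <- params$width
  w <- exp(-(distance - params$centre)^2 / (2 * m^2)) / sqrt(2 * pi * m^2)
  w[distance > params$cutoff] <- 0
  w
}

#' Centred (revised) repulsion kernel parameters
#'
#' The zonal repulsion kernel peaks at `s_r`, so neighbours immediately next
#' to an individual are weighted weakly. The revised form instead centres the
#' Gaussian on the individual itself (`centre = 0`) with width `s_r / 2`, so
#' the nearest neighbours are weighted most strongly and the weight decays
#' monotonically with distance. The truncation radius is kept at `2 * s_r`
#' so the interaction range matches the zonal form.
#'
#' @param s_r the zonal repulsion peak distance (space units), `> 0`.
#' @return A [kernel_params] object with `centre = 0`, `width = s_r / 2`,
#'   `cutoff = 2 * s_r`.
#' @export
revised_repulsion_params <- function(s_r) {
  stopifnot(is.numeric(s_r), length(s_r) == 1L, is.finite(s_r))
  if (s_r <= 0) stop("'s_r' must be > 0")
  kernel_params(centre = 0, width = s_r / 2, cutoff = 2 * s_r)
}

#' Default interaction kernel set
#'
#' Builds the three zone kernels with widths `centre / 8` and cutoffs
#' `2 * centre`. With `variant = "revised_repulsion"` the repulsion kernel
#' is replaced by the centred form of [revised_repulsion_params()]; alignment
#' and attraction are unchanged.
#'
#' @param s_r,s_al,s_a zone peak distances for repulsion, alignment and
#'   attraction (space units). Defaults 0.25, 0.5, 1.
#' @param variant `"original"` (zonal repulsion) or `"revised_repulsion"`.
#' @return A named list with `kernel_params` elements `r`, `al`, `a`.
#' @export
default_kernels <- function(s_r = 0.25, s_al = 0.5, s_a = 1,
                            variant = c("original", "revised_repulsion")) {
  variant <- match.arg(variant)
  rep_k <- if (variant == "original") {
    kernel_params(centre = s_r, width = s_r / 8, cutoff = 2 * s_r)
  } else {
    revised_repulsion_params(s_r)
  }
  list(r = rep_k,
       al = kernel_params(centre = s_al, width = s_al / 8, cutoff = 2 * s_al),
       a  = kernel_params(centre = s_a, width = s_a / 8, cutoff = 2 * s_a))
}
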