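#' Population state on the ring
#'
#' @param positions numeric vector of coordinates in `[0, L)`.
#' @param directions integer/numeric vector of travel directions, `+1`
#'   (right-moving) or `-1` (left-moving), same length as `positions`.
#' @param L ring length (space units), `> 0`.
#' @param time simulation time of the snapshot, default 0.
#' @return An object of class `population_state`.
#' @export
population_state <- function(positions, directions, L, time = 0) {
  stopifnot(is.numeric(positions), is.numeric(directions),
            length(positions) == length(directions),
            length(positions) >= 1L,
            is.numeric(L), length(L) == 1L, is.finite(L))
  if (L <= 0) stop("'L' must be > 0")
  if (any(!is.finite(positions)) || any(positions < 0) || any(positions >= L))
    stop("positions must lie in [0, L)")
  if (!all(directions %in% c(-1, 1)))
    stop("directions must be +1 or -1")
  structure(list(positions = as.numeric(positions),
                 directions = as.integer(directions),
                 L = L, time = time),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state: %d individuals on [0, %g) at t = %g; %d right-moving\n",
              length(x$positions), x$L, x$time, sum(x$directions == 1L)))
  invisible(x)
}

#' Minimal-image signed displacement on the ring
#'
#' Signed shortest displacement from `x_i` to `x_j` on a ring of length `L`,
#' in `(-L/2, L/2]`. Positive values place `x_j` in `x_i`'s right zone,
#' negative in the left zone; the exact antipode (distance `L/2`) is
#' assigned to the right by convention, and `|result|` is the interaction
#' distance. Vectorised.
#'
#' @param x_i,x_j coordinates in `[0, L)`.
#' @param L ring length, `> 0`.
#' @return Signed displacement(s) in `(-L/2, L/2]`.
#' @export
signed_displacement <- function(x_i, x_j, L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("'L' must be a positive number")
  d <- (x_j - x_i + L / 2) %% L - L / 2   # in [-L/2, L/2)
  d[d == -L / 2] <- L / 2
  d
}

# Directional zone sums for one kernel: for each individual i, the sum of
# kernel weights over neighbours split by side (R/L) and neighbour heading
# (+/-). Returns a list of four N-vectors: Rp, Rm, Lp, Lm ("m" = v_j < 0).
zone_sums <- function(W, right, left, vj_plus) {
  list(Rp = rowSums(W * (right & vj_plus)),
       Rm = rowSums(W * (right & !vj_plus)),
       Lp = rowSums(W * (left & vj_plus)),
       Lm = rowSums(W * (left & !vj_plus)))
}

# Combine directional zone sums into the own-heading force for each
# individual, per submodel. `z` is the zone_sums list, `plus` a logical
# vector (v_i == +1), `zone` is "ra" (repulsion/attraction rows) or "al".
combine_submodel <- function(z, plus, q, submodel, zone) {
  SR <- z$Rp + z$Rm
  SL <- z$Lp + z$Lm
  yp <- switch(submodel,
    M1 = if (zone == "ra") q * (SR - SL) else q * (z$Rm - z$Lp),
    M2 = if (zone == "ra") q * (SR - SL)
         else q * (z$Rm + z$Lm - z$Rp - z$Lp),
    M3 = if (zone == "ra") q * SR else q * (z$Rm - z$Rp),
    M4 = q * (z$Rm - z$Lp),
    M5 = q * z$Rm,
    stop(sprintf("unknown submodel '%s'", submodel)))
  ym <- switch(submodel,
    M1 = -yp,
    M2 = -yp,
    M3 = if (zone == "ra") q * SL else q * (z$Lp - z$Lm),
    M4 = -yp,
    M5 = q * z$Lp)
  ifelse(plus, yp, ym)
}

#' Social interaction forces under a direction-dependent rule
#'
#' For each individual, sums kernel-weighted contributions of conspecifics
#' in its repulsion, alignment and attraction zones, admitting neighbours
#' according to the active direction-dependent interaction rule (submodels
#' M1-M5), and returns the signed force matching the individual's own
#' heading. The five rules are:
#' \describe{
#'   \item{M1}{repulsion and attraction use all neighbours in the zone;
#'     alignment uses only neighbours moving toward the individual.}
#'   \item{M2}{all three forces use all neighbours.}
#'   \item{M3}{all three forces use only neighbours ahead of the
#'     individual (right zone for a right-mover, left for a left-mover).}
#'   \item{M4}{all three forces use neighbours on both sides, but only
#'     those moving toward the individual.}
#'   \item{M5}{all three forces use only neighbours ahead and moving
#'     toward the individual.}
#' }
#' A neighbour is moving toward the reference individual when it is in the
#' right zone with heading -1 or in the left zone with heading +1. Sides and
#' distances come from the minimal-image displacement
#' ([signed_displacement()]); the sums exclude the individual itself, and a
#' neighbour at exactly zero distance belongs to neither side.
#'
#' @param state a [population_state].
#' @param config a [simulation_config()] (its `q_r`, `q_al`, `q_a`,
#'   `kernels` and `submodel` fields are used).
#' @return An object of class `force_set`: list of numeric vectors `y_r`,
#'   `y_al`, `y_a`, each the force for the corresponding individual's own
#'   heading.
#' @export
compute_forces <- function(state, config) {
  stopifnot(inherits(state, "population_state"))
  submodel <- config$submodel
  if (!submodel %in% paste0("M", 1:5))
    stop(sprintf("unknown submodel '%s'", submodel))
  x <- state$positions
  v <- state$directions
  n <- length(x)
  L <- state$L
  if (n == 1L) {
    zero <- 0
    return(structure(list(y_r = zero, y_al = zero, y_a = zero),
                     class = "force_set"))
  }
  D <- outer(x, x, function(a, b) signed_displacement(a, b, L))
  dmat <- abs(D)
  right <- D > 0
  left <- D < 0
  diag(right) <- FALSE
  diag(left) <- FALSE
  vj_plus <- matrix(v > 0, n, n, byrow = TRUE)
  plus <- v > 0

  force_zone <- function(kp, q, zone) {
    if (q == 0) return(numeric(n))
    W <- kernel_weight(dmat, kp)
    diag(W) <- 0
    combine_submodel(zone_sums(W, right, left, vj_plus), plus, q,
                     submodel, zone)
  }
  structure(list(
    y_r  = force_zone(config$kernels$r,  config$q_r,  "ra"),
    y_al = force_zone(config$kernels$al, config$q_al, "al"),
    y_a  = force_zone(config$kernels$a,  config$q_a,  "ra")),
    class = "force_set")
}
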