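# Independent naive force oracle: literal double-loop transcription of the
# per-submodel force expressions (right/left zone sums with the
# direction-of-travel filters), kept deliberately separate from the
# vectorized implementation in the package.

oracle_forces <- function(state, config) {
  x <- state$positions
  v <- state$directions
  n <- length(x)
  L <- state$L
  sm <- config$submodel
  out <- list(y_r = numeric(n), y_al = numeric(n), y_a = numeric(n))
  zones <- list(r = list(q = config$q_r, kp = config$kernels$r),
                al = list(q = config$q_al, kp = config$kernels$al),
                a = list(q = config$q_a, kp = config$kernels$a))
  for (i in seq_len(n)) {
    for (zname in names(zones)) {
      q <- zones[[zname]]$q
      kp <- zones[[zname]]$kp
      SR <- SL <- SRp <- SRm <- SLp <- SLm <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        disp <- signed_displacement(x[i], x[j], L)
        w <- kernel_weight(abs(disp), kp)
        if (disp > 0) {
          SR <- SR + w
          if (v[j] > 0) SRp <- SRp + w else SRm <- SRm + w
        } else if (disp < 0) {
          SL <- SL + w
          if (v[j] > 0) SLp <- SLp + w else SLm <- SLm + w
        }
      }
      align <- zname == "al"
      if (sm == "M1") {
        if (align) { yp <- q * SRm - q * SLp; ym <- -q * SRm + q * SLp }
        else       { yp <- q * SR - q * SL;   ym <- -q * SR + q * SL }
      } else if (sm == "M2") {
        if (align) {
          yp <- q * (SRm + SLm - SRp - SLp)
          ym <- q * (SLp + SRp - SLm - SRm)
        } else { yp <- q * SR - q * SL; ym <- -q * SR + q * SL }
      } else if (sm == "M3") {
        if (align) { yp <- q * SRm - q * SRp; ym <- q * SLp - q * SLm }
        else       { yp <- q * SR;            ym <- q * SL }
      } else if (sm == "M4") {
        yp <- q * SRm - q * SLp
        ym <- -q * SRm + q * SLp
      } else if (sm == "M5") {
        yp <- q * SRm
        ym <- q * SLp
      } else stop("unknown submodel")
      out[[paste0("y_", zname)]][i] <- if (v[i] > 0) yp else ym
    }
  }
  out
}

random_state <- function(n, L = 10) {
  population_state(stats::runif(n, 0, L),
                   sample(c(-1L, 1L), n, replace = TRUE), L)
}

random_force_config <- function(submodel, variant = "original", L = 10) {
  simulation_config(n = 2, L = L, submodel = submodel,
                    kernel_variant = variant,
                    q_r = stats::runif(1, 0, 3),
                    q_al = stats::runif(1, 0, 3),
                    q_a = stats::runif(1, 0, 3))
}

mirror_state <- function(state) {
  x <- (state$L - state$positions) %% state$L
  population_state(x, -state$directions, state$L, state$time)
}

# dyadic configuration: every coordinate, shift and per-step displacement is
# an exact binary fraction, so mirrored/translated runs agree bitwise and
# heading flips cannot diverge through rounding
dyadic_config <- function(submodel, n = 24, seed = NULL, horizon = 200,
                          speed_mode = "constant", q = c(1.5, 2, 1)) {
  simulation_config(n = n, L = 8, dt = 0.0625, gamma = 0.125,
                    horizon = horizon, record_every = 5,
                    q_r = q[1], q_al = q[2], q_a = q[3],
                    submodel = submodel, speed_mode = speed_mode,
                    seed = seed)
}

dyadic_state <- function(n, L = 8) {
  population_state(sample(0:(128 * L - 1), n, replace = TRUE) / 128,
                   sample(c(-1L, 1L), n, replace = TRUE), L)
}
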