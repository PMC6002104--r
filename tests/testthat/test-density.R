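# build a trajectory object analytically, without running the simulator
synthetic_trajectory <- function(pos_matrix, dir_matrix, times, L = 10) {
  cfg <- simulation_config(n = ncol(pos_matrix), L = L,
                           horizon = length(times) - 1L, record_every = 1)
  structure(list(times = times, positions = pos_matrix,
                 directions = dir_matrix, config = cfg),
            class = "swarm_trajectory")
}

test_that("single-individual density peaks at K(0)/h over its position", {
  got <- kde_density(positions = 3, grid = 3, h = 0.1, L = 10)
  expect_equal(got, stats::dnorm(0) / 0.1, tolerance = 1e-14)
  expect_equal(got, 3.9894, tolerance = 1e-4)
})

test_that("wrapped kernel density integrates to one on the ring", {
  set.seed(41)
  grid <- seq(0, 10, length.out = 2001)[-2001]
  for (n in c(1, 7, 200)) {
    rho <- kde_density(runif(n, 0, 10), grid, h = 0.1, L = 10)
    expect_true(all(rho >= 0))
    # trapezoid on the ring == mean * L for equally spaced periodic grid
    expect_equal(mean(rho) * 10, 1, tolerance = 1e-6)
  }
  # a cluster straddling the seam keeps its mass (no boundary artifact)
  rho <- kde_density(c(9.95, 0.02, 0.08), grid, h = 0.1, L = 10)
  expect_equal(mean(rho) * 10, 1, tolerance = 1e-6)
  expect_error(kde_density(numeric(0), grid, 0.1, 10), "non-empty")
})

test_that("dense uniform positions recover the flat density 1/L", {
  set.seed(43)
  grid <- seq(0, 10, length.out = 51)[-51]
  rho <- kde_density(runif(1e5, 0, 10), grid, h = 0.1, L = 10)
  expect_true(all(abs(rho - 0.1) < 0.01))
})

test_that("space-time field stacks per-frame densities and mirrors correctly", {
  set.seed(47)
  pos <- rbind(runif(20, 0, 10), runif(20, 0, 10), runif(20, 0, 10))
  dir <- matrix(sample(c(-1L, 1L), 60, TRUE), 3)
  tr <- synthetic_trajectory(pos, dir, times = c(0, 1, 2))
  grid <- seq(0, 10, length.out = 200)[1:199] # include 0 so reversal maps grid onto itself
  fld <- spacetime_density(tr, grid = grid, h = 0.1)
  expect_identical(dim(fld$values), c(3L, 199L))
  expect_equal(fld$values[2, ], kde_density(pos[2, ], grid, 0.1, 10),
               tolerance = 1e-12)
  # mirrored trajectory -> spatially reversed field
  trm <- synthetic_trajectory((10 - pos) %% 10, -dir, times = c(0, 1, 2))
  fldm <- spacetime_density(trm, grid = grid, h = 0.1)
  rev_idx <- c(1L, 199:2) # grid point 0 is self-mirror; others reverse
  expect_equal(fldm$values, fld$values[, rev_idx], tolerance = 1e-9)
})

test_that("max-normalization scales the global maximum to one and is idempotent", {
  set.seed(49)
  tr <- synthetic_trajectory(rbind(runif(15, 4, 6), runif(15, 4, 6)),
                             matrix(1L, 2, 15), times = c(0, 1))
  fld <- spacetime_density(tr)
  nf <- normalize_max(fld)
  expect_equal(max(nf$values), 1)
  expect_true(all(nf$values >= 0))
  expect_equal(which.max(nf$values), which.max(fld$values))
  nf2 <- normalize_max(nf)
  expect_equal(nf2$values, nf$values, tolerance = 1e-14)
  fld0 <- fld
  fld0$values[] <- 0
  expect_error(normalize_max(fld0), "positive")
})

test_that("diagnostics recover the parameters of analytically built trajectories", {
  times <- seq(0, 50, by = 0.5)
  nf <- length(times)
  # rigidly translating compact cluster at speed gamma = 0.1
  base <- seq(4.8, 5.2, length.out = 20)
  pos <- t(vapply(times, function(t) (base + 0.1 * t) %% 10,
                  numeric(20)))
  tr <- synthetic_trajectory(pos, matrix(1L, nf, 20), times)
  d <- diagnostics(tr, window = 5)
  expect_true(all(d$polarization == 1))
  expect_equal(d$drift_speed[!is.na(d$drift_speed)],
               rep(0.1, sum(!is.na(d$drift_speed))), tolerance = 1e-6)
  expect_equal(d$centroid[1], 5, tolerance = 1e-6)
  expect_true(all(d$aggregation_width < 0.2))
  # static cluster: zero drift, stable width
  pos0 <- matrix(rep(base, each = nf), nf)
  d0 <- diagnostics(synthetic_trajectory(pos0, matrix(1L, nf, 20), times),
                    window = 5)
  expect_true(all(abs(d0$drift_speed[!is.na(d0$drift_speed)]) < 1e-10))
  # two counter-propagating clusters: zero polarization, stationary centroid
  # two counter-propagating clusters: balanced headings at all times
  posa <- t(vapply(times, function(t) {
    c((base + 0.1 * t) %% 10, (base + 2.5 - 0.1 * t) %% 10)
  }, numeric(40)))
  dirs <- cbind(matrix(1L, nf, 20), matrix(-1L, nf, 20))
  d2 <- diagnostics(synthetic_trajectory(posa, dirs, times), window = 5)
  expect_true(all(d2$polarization == 0))
})

test_that("pattern speed recovers the translation velocity of a rigid cluster", {
  times <- seq(0, 50, by = 0.5)
  nf <- length(times)
  base <- seq(4.8, 5.2, length.out = 30)
  grid <- seq(0, 10, length.out = 251)[-251]
  for (v in c(0.1, -0.1, 0)) {
    pos <- t(vapply(times, function(t) (base + v * t) %% 10, numeric(30)))
    tr <- synthetic_trajectory(pos, matrix(1L, nf, 30), times)
    fld <- spacetime_density(tr, grid = grid)
    expect_equal(pattern_speed(fld), v, tolerance = 0.05 + 1e-9)
  }
  # counter-moving individuals, rigidly translating profile: the pattern
  # speed sees the profile motion, not the headings
  posm <- t(vapply(times, function(t) (base + 0.1 * t) %% 10, numeric(30)))
  dirm <- matrix(rep(c(1L, -1L), length.out = 30), nf, 30, byrow = TRUE)
  fldm <- spacetime_density(synthetic_trajectory(posm, dirm, times),
                            grid = grid)
  expect_equal(pattern_speed(fldm), 0.1, tolerance = 0.05)
})

test_that("peak counting tracks the number of aggregations per frame", {
  grid <- seq(0, 10, length.out = 400)[-400]
  two <- c(rnorm(50, 2, 0.15) %% 10, rnorm(50, 7, 0.15) %% 10)
  one <- rnorm(100, 5, 0.15) %% 10
  tr <- synthetic_trajectory(rbind(two, one),
                             matrix(1L, 2, 100), times = c(0, 1))
  fld <- spacetime_density(tr, grid = grid)
  expect_identical(count_density_peaks(fld), c(2L, 1L))
  # a flat field is a single ring-spanning plateau
  flat <- fld
  flat$values[] <- 1
  expect_identical(count_density_peaks(flat), c(1L, 1L))
})

test_that("local polarization sees band order that global polarization misses", {
  # two tight counter-moving groups: globally balanced, locally ordered
  st <- population_state(c(seq(1.9, 2.1, length.out = 20),
                           seq(6.9, 7.1, length.out = 20)),
                         c(rep(1L, 20), rep(-1L, 20)), L = 10)
  expect_equal(local_polarization(st), 1)
  expect_equal(abs(mean(st$directions)), 0)
  # same positions, alternating headings: no local order
  st2 <- population_state(st$positions,
                          rep(c(1L, -1L), 20), L = 10)
  expect_lt(local_polarization(st2), 0.2)
  # uniformly right-moving population is fully ordered at any radius
  set.seed(61)
  st3 <- population_state(runif(50, 0, 10), rep(1L, 50), 10)
  expect_equal(local_polarization(st3, radius = 1), 1)
})

test_that("direction-conditional density isolates one heading subpopulation", {
  pos <- rbind(c(rnorm(30, 2, 0.1) %% 10, rnorm(30, 7, 0.1) %% 10))
  dir <- rbind(c(rep(1L, 30), rep(-1L, 30)))
  tr <- synthetic_trajectory(pos, dir, times = 0)
  grid <- seq(0, 10, length.out = 500)[-500]
  fr <- direction_density(tr, 1, grid = grid)
  fl <- direction_density(tr, -1, grid = grid)
  expect_equal(fr$grid[which.max(fr$values[1, ])], 2, tolerance = 0.1)
  expect_equal(fl$grid[which.max(fl$values[1, ])], 7, tolerance = 0.1)
  expect_equal(mean(fr$values[1, ]) * 10, 1, tolerance = 1e-6)
  # a frame with no individuals of the heading gives a zero row
  tr_all_right <- synthetic_trajectory(pos, rbind(rep(1L, 60)), times = 0)
  expect_true(all(direction_density(tr_all_right, -1,
                                    grid = grid)$values == 0))
})

test_that("dominant peak width follows the spread of the largest aggregation", {
  grid <- seq(0, 10, length.out = 500)[-500]
  narrow <- rnorm(200, 5, 0.1) %% 10
  wide <- rnorm(200, 5, 0.4) %% 10
  seam <- (rnorm(200, 0, 0.4)) %% 10      # straddles the ring seam
  tr <- synthetic_trajectory(rbind(narrow, wide, seam),
                             matrix(1L, 3, 200), times = c(0, 1, 2))
  w <- dominant_peak_width(spacetime_density(tr, grid = grid))
  expect_lt(w[1], w[2])
  expect_equal(w[3], w[2], tolerance = 0.35)  # wrap does not split the peak
  expect_true(all(w > 0 & w <= 10))
})
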