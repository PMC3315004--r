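test_that("paradigm generator emits the configured event mix", {
  p <- build_paradigm(seed = 7)
  expect_equal(sum(p$events$kind == "grip"), 100)
  expect_equal(sum(p$events$kind == "null"), 60)
  expect_equal(nrow(p$events), 160)
  # counterbalanced: every level appears exactly reps_per_level times
  for (seed in c(1, 42, 9000)) {
    p2 <- build_paradigm(seed = seed)
    expect_equal(unname(table(p2$events$force[p2$events$kind == "grip"])),
                 rep(20L, 5), ignore_attr = TRUE)
  }
  # onsets strictly increasing at the SOA
  expect_true(all(diff(p$events$onset) > 0))
  expect_equal(diff(p$events$onset), rep(3.77, 159))
})

test_that("degenerate paradigms and invalid configurations behave", {
  p1 <- build_paradigm(levels = 50, reps_per_level = 1, n_null = 0, seed = 1)
  expect_equal(nrow(p1$events), 1)
  expect_equal(p1$events$onset, 0)
  expect_error(build_paradigm(soa = 0), "SOA")
  expect_error(build_paradigm(levels = numeric(0)), "force level")
  expect_error(build_paradigm(reps_per_level = 0), "reps_per_level")
})

test_that("input functions impulse-code grips and mean-centre force", {
  p <- build_paradigm(seed = 3)
  u <- build_inputs(p)
  expect_equal(sum(u$u[1, ] > 0), 100)
  # unit-area driving impulses
  expect_equal(sum(u$u[1, ]) * u$dt, 100)
  # modulatory areas sum to zero after centring
  expect_lt(abs(sum(u$u[2, ]) * u$dt), 1e-10)
  # nulls contribute nothing: nonzero bins identical across channels
  expect_true(all(which(u$u[2, ] != 0) %in% which(u$u[1, ] != 0)))
  expect_error(build_inputs(p, dt = 0), "dt")
  expect_error(build_inputs(p, dt = p$tr / 4), "TR/8")

  empty <- build_paradigm(levels = 50, reps_per_level = 1, n_null = 0, seed = 1)
  empty$events <- empty$events[0, ]
  expect_true(all(build_inputs(empty)$u == 0))

  raw <- build_inputs(p, center = FALSE)
  expect_gt(sum(raw$u[2, ]) * raw$dt, 0)
})

test_that("neural derivative matches the bilinear state equation", {
  # hand-evaluated 2-node case
  p <- two_region_params(a21 = 0.2, b21 = 0.3, c1 = 1)
  d <- neural_derivative(c(1, 1), p, 1)
  expect_equal(d, c(0.5, 0.0), ignore_attr = TRUE)
  # fixed point at the origin and pure-A regime
  expect_equal(neural_derivative(c(0, 0), p, 0), c(0, 0), ignore_attr = TRUE)
  x <- c(0.3, -0.7)
  expect_equal(neural_derivative(x, p, 0), drop(p$A %*% x),
               ignore_attr = TRUE)
  expect_error(neural_derivative(c(1, 1, 1), p, 1), "A is 2x2")
  expect_error(neural_derivative(c(1, 1), p, c(1, 0)), "input channels")
})

test_that("neural integration matches closed forms", {
  # decoupled exponential decay
  p <- dcm_params(diag(-0.5, 2), m = 1)
  inputs <- list(u = matrix(0, 1, 100), dt = 0.05)
  tr <- integrate_neural(p, inputs, x0 = c(1, 0))
  expect_equal(tr$x[1, ], exp(-0.5 * tr$times), tolerance = 1e-6)
  expect_equal(tr$x[2, ], rep(0, 100))

  # constant input, B = 0: x(t) = A^-1 (e^{At} - I) C u
  A <- matrix(c(-0.6, 0.2, 0.1, -0.4, -0.1, 0.15, 0.05, 0.2, -0.5), 3, 3)
  Cc <- matrix(c(1, 0.5, 0), 3, 1)
  p3 <- dcm_params(A, C = Cc, m = 1)
  inputs3 <- list(u = matrix(1, 1, 200), dt = 0.05)
  tr3 <- integrate_neural(p3, inputs3, x0 = rep(0, 3))
  for (tj in c(50, 120, 200)) {
    t_ <- (tj - 1) * 0.05
    eAt <- as.matrix(Matrix::expm(A * t_))
    closed <- solve(A, (eAt - diag(3)) %*% Cc)
    expect_equal(tr3$x[, tj], drop(closed), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }

  # zero input from the origin stays at the origin
  tr0 <- integrate_neural(p3, list(u = matrix(0, 1, 50), dt = 0.1))
  expect_true(all(tr0$x == 0))
})

test_that("superposition holds in the linear regime", {
  p <- two_region_params(b21 = 0)
  n_bins <- 400
  dt <- 0.05
  u1 <- matrix(0, 1, n_bins); u1[1, 10] <- 1 / dt
  u2 <- matrix(0, 1, n_bins); u2[1, 150] <- 1 / dt
  x1 <- integrate_neural(p, list(u = u1, dt = dt))$x
  x2 <- integrate_neural(p, list(u = u2, dt = dt))$x
  x12 <- integrate_neural(p, list(u = u1 + u2, dt = dt))$x
  expect_equal(x12, x1 + x2, tolerance = 1e-8)
})

test_that("trajectories stay bounded over the full paradigm at prior means", {
  # prior-mean parameters: A = -0.5 I, B = 0, C = 0 plus a driving weight 1
  p <- build_paradigm(seed = 5)
  u <- build_inputs(p)
  n <- 8
  A <- diag(-0.5, n)
  C <- matrix(0, n, 2); C[1:4, 1] <- 1
  tr <- integrate_neural(dcm_params(A, C = C, m = 2), u)
  expect_true(all(is.finite(tr$x)))
  expect_lt(max(abs(tr$x)), 50)
})

test_that("integrator refinement is consistent with a higher-order scheme", {
  p <- two_region_params()
  # input held piecewise constant on the coarsest grid so every refinement
  # integrates the same continuous-time problem
  coarse <- rep(c(1, 0, -0.5, 0.25, 0), each = 8)   # 10 s at dt = 0.25
  traj_at <- function(dt) {
    rep_each <- round(0.25 / dt)
    u <- matrix(rep(coarse, each = rep_each), 1)
    x <- integrate_neural(p, list(u = u, dt = dt))$x
    x[, seq(1, ncol(u), by = rep_each)]
  }
  c1 <- max(abs(traj_at(0.25) - traj_at(0.125)))
  c2 <- max(abs(traj_at(0.125) - traj_at(0.0625)))
  expect_lt(c2, c1 / 4)
})

test_that("diverging systems raise a divergence error naming the bin", {
  A <- matrix(c(-0.5, 2, 2, -0.5), 2, 2)  # strongly unstable off-diagonals
  p <- dcm_params(A, C = matrix(c(1, 0), 2, 1), m = 1)
  u <- matrix(1e6, 1, 5000)
  expect_error(integrate_neural(p, list(u = u, dt = 0.5)), "time bin")
})

test_that("trajectory tables round-trip through TSV", {
  p <- two_region_params()
  u <- list(u = matrix(0, 1, 30), dt = 0.1)
  tr <- integrate_neural(p, u, x0 = c(1, 0.5))
  path <- tempfile(fileext = ".tsv")
  write_timeseries(tr, path)
  back <- read_timeseries(path)
  expect_equal(unname(back$y), unname(t(tr$x)), tolerance = 1e-12)
  expect_equal(back$times, tr$times)
})
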