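test_that("rest is a fixed point of the haemodynamic equations", {
  d <- haemo_step(c(0, 1, 1, 1), z = 0)
  expect_equal(unname(d), rep(0, 4))
  # at f = 1 the extraction term reduces to E0: dq/dt = (E0/E0 - q)/tau
  hp <- haemo_params()
  d2 <- haemo_step(c(0, 1, 1, 2), z = 0, hp)
  expect_equal(unname(d2["q"]), (1 - 2) / hp$tau)
  expect_error(haemo_step(c(0, -1, 1, 1), 0), "strictly positive")
  expect_error(haemo_step(c(0, 1, 0, 1), 0), "strictly positive")
})

test_that("sustained activity raises inflow which returns to rest", {
  skip_if_not_installed("deSolve")
  hp <- haemo_params()
  rhs <- function(t, y, parms) {
    z <- if (t < 10) 1 else 0
    list(unname(haemo_step(y, z, hp)))
  }
  sol <- deSolve::ode(c(s = 0, f = 1, v = 1, q = 1),
                      seq(0, 40, by = 0.05), rhs, NULL)
  f <- sol[, "f"]
  expect_gt(max(f[sol[, "time"] < 10]), 1)     # flow rises under drive
  expect_lt(abs(f[length(f)] - 1), 0.02)       # and returns toward rest
})

test_that("BOLD observation is zero at rest and linear in V0", {
  traj <- rbind(s = rep(0, 5), f = 1, v = 1, q = 1)
  expect_equal(bold_observe(traj), rep(0, 5))
  traj2 <- rbind(s = 0, f = c(1, 1.2, 1.1), v = c(1, 1.1, 1.05),
                 q = c(1, 0.9, 0.95))
  y1 <- bold_observe(traj2, haemo_params(V0 = 0.04))
  y3 <- bold_observe(traj2, haemo_params(V0 = 0.12))
  expect_equal(y3, 3 * y1, tolerance = 1e-12)
})

test_that("impulse BOLD response peaks 3-8 s after the event", {
  paradigm <- build_paradigm(levels = 50, reps_per_level = 1, n_null = 0,
                             soa = 12, tr = 0.8, n_volumes = 15, seed = 1)
  p <- dcm_params(matrix(-0.5), C = matrix(c(1, 0), 1, 2), m = 2)
  ts <- simulate_bold(p, paradigm = paradigm, noise_sd = 0, dt = 0.1)
  peak_t <- ts$times[which.max(ts$y[, 1])]
  expect_gte(peak_t, 3)
  expect_lte(peak_t, 8)
})

test_that("simulated BOLD is reproducible and noise is calibrated", {
  paradigm <- short_paradigm(seed = 2)
  p <- two_region_params(m = 2)
  a <- simulate_bold(p, paradigm = paradigm, noise_sd = 0.4, seed = 11)
  b <- simulate_bold(p, paradigm = paradigm, noise_sd = 0.4, seed = 11)
  expect_identical(a$y, b$y)

  # with no input and no noise the series is identically zero
  p0 <- dcm_params(diag(-0.5, 2), m = 2)
  z <- simulate_bold(p0, paradigm = paradigm, noise_sd = 0)
  expect_true(all(z$y == 0))

  # injected noise sd matches its target at T = 196, n = 8
  paradigm_full <- build_paradigm(seed = 3)
  p8 <- dcm_params(diag(-0.5, 8),
                   C = cbind(c(1, 1, 1, 1, 0, 0, 0, 0), 0), m = 2)
  clean <- simulate_bold(p8, paradigm = paradigm_full, noise_sd = 0)
  noisy <- simulate_bold(p8, paradigm = paradigm_full, noise_sd = 0.5,
                         seed = 21)
  expect_equal(sd(noisy$y - clean$y), 0.5, tolerance = 0.05)
})

test_that("RK4 forward solution agrees with a dense-grid reference", {
  skip_if_not_installed("deSolve")
  # smooth inputs (an adaptive reference solver cannot track the one-bin
  # event impulses, so the comparison uses band-limited drive instead)
  paradigm <- short_paradigm(seed = 4, n_volumes = 8)
  dt <- paradigm$tr / 16
  n_bins <- ceiling(paradigm$n_volumes * paradigm$tr / dt)
  tt <- (seq_len(n_bins) - 1) * dt
  inputs <- list(u = rbind(0.5 + 0.5 * sin(2 * pi * tt / 12),
                           0.1 * sin(2 * pi * tt / 7)), dt = dt)
  p <- two_region_params(m = 2)
  hp <- haemo_params()
  ts <- simulate_bold(p, hp, paradigm, noise_sd = 0, inputs = inputs)

  # independent route: chain an adaptive solver bin by bin with the input
  # held constant over each bin, exactly the problem the RK4 grid solves
  clamp <- function(h) c(h[1], pmax(h[2:3], 1e-8), h[4])
  rhs <- function(t, y, parms) {
    x <- y[1:2]
    dx <- neural_derivative(x, p, parms)
    dh <- c(haemo_step(clamp(y[3:6]), x[1], hp),
            haemo_step(clamp(y[7:10]), x[2], hp))
    list(c(dx, dh))
  }
  y <- c(0, 0, 0, 1, 1, 1, 0, 1, 1, 1)
  states <- matrix(NA_real_, n_bins, 10)
  for (k in seq_len(n_bins)) {
    states[k, ] <- y
    sol <- deSolve::ode(y, c(0, dt), rhs, inputs$u[, k], method = "ode45",
                        rtol = 1e-10, atol = 1e-10)
    y <- sol[2, -1]
  }
  vol_bins <- round((seq_len(paradigm$n_volumes) - 1) * paradigm$tr / dt) + 1
  ref <- 100 * cbind(bold_observe(t(states[vol_bins, 3:6]), hp),
                     bold_observe(t(states[vol_bins, 7:10]), hp))
  expect_equal(unname(ts$y), unname(ref), tolerance = 1e-5)
})

test_that("first eigenvariate summarises voxel sets as expected", {
  t_ <- 40
  g <- sin(seq(0, 4 * pi, length.out = t_))
  # single column: proportional with positive correlation
  ev1 <- first_eigenvariate(cbind(g))
  expect_gt(cor(ev1, g), 0.999)
  # rank-1 matrix g w': proportional to g up to sign resolved positive
  w <- c(0.5, 1, 2, 0.25)
  ev <- first_eigenvariate(g %o% w)
  expect_equal(abs(cor(ev, g)), 1, tolerance = 1e-12)
  expect_gt(sum(ev * rowMeans(g %o% w)), 0)
  # symmetric columns g and -g still yield a defined, sign-resolved answer
  ev2 <- first_eigenvariate(cbind(g, -0.5 * g))
  expect_equal(abs(cor(ev2, g)), 1, tolerance = 1e-12)
  # idempotence up to scale
  ev3 <- first_eigenvariate(cbind(ev))
  expect_equal(cor(ev3, ev), 1, tolerance = 1e-12)
  expect_error(first_eigenvariate(matrix(0, 10, 3)), "all-zero")
})

test_that("preprocessing scales, filters drifts, and keeps task bands", {
  tr <- 3.12
  t_ <- 196
  times <- (seq_len(t_) - 1) * tr
  make_ts <- function(y) {
    structure(list(y = cbind(y), tr = tr, times = times, meta = list()),
              class = "bold_timeseries")
  }
  # constant series scaled to the target mean and untouched by the filter
  const <- preprocess_ts(make_ts(rep(50, t_)), target_mean = 100)
  expect_equal(unname(const$y[, 1]), rep(100, t_))

  # slow drift (256 s period) almost removed
  slow <- sin(2 * pi * times / 256)
  f_slow <- preprocess_ts(make_ts(100 + slow))
  expect_lt(sd(f_slow$y[, 1]), 0.1 * sd(slow))

  # task-band oscillation (32 s period) preserved
  fast <- sin(2 * pi * times / 32)
  f_fast <- preprocess_ts(make_ts(100 + fast))
  expect_equal(sd(f_fast$y[, 1]), sd(fast), tolerance = 0.05)

  expect_error(preprocess_ts(make_ts(rep(0, t_))), "grand mean")
  expect_error(preprocess_ts(make_ts(rep(1, t_)), cutoff = 2), "twice the TR")
})
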