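test_that("free-energy components have their closed forms", {
  # identical Gaussians have zero KL
  S <- matrix(c(2, 0.3, 0.3, 1), 2, 2)
  expect_equal(kl_gaussian(c(1, -1), S, c(1, -1), S), 0, tolerance = 1e-12)
  # KL against a wider prior matches the explicit formula
  S0 <- diag(c(4, 4))
  mu <- c(0.5, 0); mu0 <- c(0, 0)
  direct <- 0.5 * (sum(diag(solve(S0) %*% S)) +
                     t(mu - mu0) %*% solve(S0) %*% (mu - mu0) - 2 +
                     determinant(S0)$modulus - determinant(S)$modulus)
  expect_equal(kl_gaussian(mu, S, mu0, S0), as.numeric(direct),
               tolerance = 1e-12)
  expect_error(kl_gaussian(c(0, 0), matrix(c(1, 2, 2, 1), 2), mu0, S0),
               "positive definite")

  # doubling the noise precision on fixed residuals changes the accuracy
  # by N log sqrt(2) minus the extra quadratic penalty
  r <- c(0.5, -1, 0.25, 2)
  lam <- 0.8
  gain <- gaussian_accuracy(r, 2 * lam) - gaussian_accuracy(r, lam)
  expect_equal(gain, length(r) * log(sqrt(2)) - lam / 2 * sum(r^2),
               tolerance = 1e-12)
  # zero residuals at unit precision leave only the normalising constant
  expect_equal(gaussian_accuracy(numeric(3) , 1), -3 / 2 * log(2 * pi))
  expect_equal(free_energy(-10, 3), -13)
})

test_that("pure-noise data with zero inputs leave the posterior at the prior", {
  set.seed(4)
  labs <- c("R1_L", "R2_R")
  ts <- structure(list(y = matrix(rnorm(80 * 2), 80, 2), tr = 3.12,
                       times = (0:79) * 3.12, meta = list()),
                  class = "bold_timeseries")
  inputs <- list(u = matrix(0, 2, 80 * 16), dt = 3.12 / 16)
  spec <- free_model_spec(labs)
  fit <- invert_model(ts, inputs, spec, settings = quick_settings())
  # with no input the model is flat: posterior returns exactly to the prior
  expect_equal(unname(fit$posterior_mean), rep(0, length(fit$posterior_mean)),
               tolerance = 1e-8)
  pt <- fit$param_table
  expect_equal(fit$complexity, 0, tolerance = 1e-6)
  expect_equal(unname(diag(fit$posterior_cov)), pt$var, tolerance = 1e-6)
})

test_that("posterior covariance is symmetric positive semidefinite", {
  co <- sample_cohort(n = 2, regions = reduced_region_set(), seed = 31)
  s <- co$subjects[[1]]
  sp <- enumerate_model_space(reduced_region_set())
  fit <- invert_model(preprocess_ts(s$bold), build_inputs(s$paradigm),
                      sp$models[[10]], settings = quick_settings())
  expect_true(fit$converged)
  expect_equal(fit$posterior_cov, t(fit$posterior_cov), tolerance = 1e-10)
  ev <- eigen(fit$posterior_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_true(is.finite(fit$free_energy))
})

test_that("the generating structure outranks a model missing its key path", {
  sp_full <- free_model_spec(c("M1_L", "M1_R", "SMA_L"))
  sp_cut <- sp_full
  sp_cut$a_mask["M1_R", "M1_L"] <- 0L   # sever the generating connection
  truth <- three_region_truth()
  truth$A["M1_R", "M1_L"] <- 0.35       # make the path matter
  paradigm <- build_paradigm(seed = 50, n_volumes = 98)
  inputs <- build_inputs(paradigm)
  wins <- 0
  for (seed in 1:5) {
    clean <- simulate_bold(truth, paradigm = paradigm, noise_sd = 0,
                           inputs = inputs)
    nsd <- sd(sweep(clean$y, 2, colMeans(clean$y)))
    ts <- simulate_bold(truth, paradigm = paradigm, noise_sd = nsd,
                        seed = 60 + seed, inputs = inputs)
    f_full <- invert_model(ts, inputs, sp_full, settings = quick_settings())
    f_cut <- invert_model(ts, inputs, sp_cut, settings = quick_settings())
    if (f_full$free_energy > f_cut$free_energy) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("masked-out parameters are pinned at the prior mean", {
  sp <- free_model_spec(c("M1_L", "M1_R", "SMA_L"))
  sp$a_mask["SMA_L", "M1_R"] <- 0L
  expect_false("A[SMA_L,M1_R]" %in%
                 gripdcm:::param_table(sp, prior_spec())$name)
})

test_that("sign-flipping a region flips its couplings but not the evidence", {
  truth <- three_region_truth()
  truth$C <- truth$C * 0.01   # weak drive keeps the observation near-linear
  paradigm <- build_paradigm(seed = 77, n_volumes = 98)
  inputs <- build_inputs(paradigm)
  ts <- simulate_bold(truth, paradigm = paradigm, noise_sd = 0.001,
                      seed = 5, inputs = inputs)
  spec <- free_model_spec(c("M1_L", "M1_R", "SMA_L"))
  fit <- invert_model(ts, inputs, spec, settings = quick_settings())
  ts_f <- ts
  ts_f$y[, 2] <- -ts_f$y[, 2]
  fit_f <- invert_model(ts_f, inputs, spec, settings = quick_settings())
  expect_lt(abs(fit_f$free_energy - fit$free_energy), 1e-2)
  expect_lt(abs(fit_f$posterior_mean["A[M1_R,M1_L]"] +
                  fit$posterior_mean["A[M1_R,M1_L]"]), 1e-3)
  expect_lt(abs(fit_f$posterior_mean["A[M1_L,M1_R]"] +
                  fit$posterior_mean["A[M1_L,M1_R]"]), 1e-3)
  expect_lt(abs(fit_f$posterior_mean["A[SMA_L,M1_L]"] -
                  fit$posterior_mean["A[SMA_L,M1_L]"]), 1e-3)
})

test_that("doubling the session length never hurts the true model", {
  truth <- three_region_truth()
  Fs <- sapply(c(49, 98), function(nv) {
    paradigm <- build_paradigm(seed = 13, n_volumes = nv)
    inputs <- build_inputs(paradigm)
    ts <- simulate_bold(truth, paradigm = paradigm, noise_sd = 0.01,
                        seed = 2, inputs = inputs)
    spec <- free_model_spec(c("M1_L", "M1_R", "SMA_L"),
                            b_mask = (truth$B[[2]] != 0) * 1L)
    invert_model(ts, inputs, spec, settings = quick_settings())$free_energy
  })
  # F scales with the data: more near-noiseless volumes add evidence
  expect_gt(Fs[2], Fs[1])
})
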