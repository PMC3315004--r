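test_that("the cohort generator reproduces the study's shape", {
  co <- sample_cohort(n = 27, seed = 8, simulate = FALSE)
  expect_length(co$subjects, 27)
  expect_true(all(co$ages >= 19 & co$ages <= 77))
  expect_equal(co$regions$n, 8)
  # every subject carries truth, a paradigm and both MEP conditions
  s <- co$subjects[[5]]
  expect_s3_class(s$truth, "dcm_params")
  expect_equal(sum(s$paradigm$events$kind == "grip"), 100)
  expect_equal(length(s$meps$rest$test_amplitudes), 10)
  expect_equal(length(s$meps$active$conditioned_amplitudes), 10)
  # driving input confined to the left hemisphere, at the reported weights
  expect_equal(unname(s$truth$C[, 1]),
               c(1.26, 0, 0.1, 0, 0.04, 0, 0.08, 0))
})

test_that("cohorts are bit-for-bit reproducible given the seed", {
  a <- sample_cohort(n = 3, regions = reduced_region_set(), seed = 77)
  b <- sample_cohort(n = 3, regions = reduced_region_set(), seed = 77)
  expect_identical(a$ages, b$ages)
  for (k in 1:3) {
    expect_identical(a$subjects[[k]]$truth$A, b$subjects[[k]]$truth$A)
    expect_identical(a$subjects[[k]]$bold$y, b$subjects[[k]]$bold$y)
    expect_identical(a$subjects[[k]]$change_ihi, b$subjects[[k]]$change_ihi)
  }
  c_ <- sample_cohort(n = 3, regions = reduced_region_set(), seed = 78)
  expect_false(identical(a$subjects[[1]]$bold$y, c_$subjects[[1]]$bold$y))
})

test_that("type 1 connections cross zero at the configured ages", {
  eff <- default_effect_spec()
  cons <- eff$connections
  t1 <- cons[cons$pattern == "type1", ]
  expect_true(all(t1$to == "M1_R"))
  lo <- t1$intercept + t1$slope * (19 - eff$age_ref)
  hi <- t1$intercept + t1$slope * (77 - eff$age_ref)
  expect_true(all(lo < 0 & hi > 0))
  t2 <- cons[cons$pattern == "type2", ]
  expect_true(all(t2$intercept + t2$slope * (19 - eff$age_ref) > 0))
  expect_true(all(t2$slope > 0))

  # a type1 line that cannot cross zero is a configuration error
  bad <- eff
  bad$connections$intercept[bad$connections$pattern == "type1"] <- 1
  expect_error(sample_cohort(n = 3, effects = bad, simulate = FALSE),
               "configuration error")
})

test_that("null effects yield no systematic age relationship", {
  r2 <- replicate(20, NA_real_)
  for (k in 1:20) {
    co <- sample_cohort(n = 27, effects = null_effect_spec(), seed = 300 + k,
                        simulate = FALSE)
    r2[k] <- correlate(co$ages, cohort_truth(co))$r2
  }
  expect_lt(mean(r2), 0.1)
})

test_that("the generator recovers its calibrated IHI-age association", {
  # change-IHI vs age is calibrated to r2 = 0.45 at the TMS subset size
  r2 <- sapply(1:20, function(k) {
    co <- sample_cohort(n = 19, seed = 400 + k, simulate = FALSE)
    chihi <- vapply(co$subjects, function(s) s$change_ihi, numeric(1))
    correlate(co$ages, chihi)$r2
  })
  expect_lt(abs(mean(r2) - 0.45), 0.15)
})

test_that("ground-truth couplings realise their calibrated age effects", {
  # LM1 -> RM1 is calibrated to r2 = 0.64 at the full cohort size
  r2 <- sapply(1:12, function(k) {
    co <- sample_cohort(n = 27, seed = 500 + k, simulate = FALSE)
    correlate(co$ages, cohort_truth(co))$r2
  })
  expect_lt(abs(mean(r2) - 0.64), 0.12)
})

test_that("inverting the generating model recovers the age slope's sign", {
  # end-to-end: cohort -> winning-family maximal model inversion ->
  # LM1->RM1 coupling vs age; the generator plants a positive slope
  reg <- reduced_region_set()
  mod <- maximal_model(winning_family_models(enumerate_model_space(reg)))
  positive <- 0
  for (k in 1:10) {
    co <- sample_cohort(n = 12, regions = reg, seed = 8200 + k)
    est <- vapply(co$subjects, function(s) {
      fit <- invert_model(preprocess_ts(s$bold), build_inputs(s$paradigm),
                          mod)
      bma_subject(list(fit))$params[["A[M1_R,M1_L]"]]
    }, numeric(1))
    if (correlate(co$ages, est)$slope > 0) positive <- positive + 1
  }
  expect_gte(positive, 9)
})

test_that("cohorts serialise to a plain-text directory", {
  co <- sample_cohort(n = 2, regions = reduced_region_set(), seed = 12)
  dir <- file.path(tempdir(), "cohort_test")
  manifest <- write_cohort(co, dir)
  expect_true(file.exists(manifest))
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_equal(nrow(man$subjects), 2)
  ts <- read_timeseries(file.path(dir, man$subjects$bold[1]))
  expect_equal(unname(ts$y), unname(co$subjects[[1]]$bold$y),
               tolerance = 1e-6)
  meps <- read_mep_trials(file.path(dir, man$subjects$mep[1]))
  expect_length(meps, 2)
  unlink(dir, recursive = TRUE)
})
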