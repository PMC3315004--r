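# Group-average intrinsic coupling during grip (1/s), entry [i, j] = source
# j -> target i; used as the generator's baseline connectivity.
GRIP_COUPLING_TABLE <- local({
  labs <- c("M1_L", "M1_R", "SMA_L", "SMA_R", "PMd_L", "PMd_R", "PMv_L", "PMv_R")
  m <- matrix(c(
      NA,   0.01,  0.06,  0.02,  0.02,  0.02,  0.03,  0.02,
      0.00,   NA, -0.03, -0.02, -0.03, -0.02, -0.02, -0.03,
      0.16, 0.01,    NA,  0.02,  0.02,  0.01,  0.03,  0.01,
      0.13, 0.01,  0.06,    NA,  0.04,  0.02,  0.05,  0.02,
      0.15, 0.00,  0.06,  0.02,    NA,  0.02,  0.04,  0.02,
      0.11, 0.01,  0.07,  0.04,  0.05,    NA,  0.05,  0.03,
      0.14, 0.01,  0.05,  0.02,  0.03,  0.01,    NA,  0.01,
      0.11, 0.00,  0.07,  0.04,  0.06,  0.04,  0.06,    NA),
    8, 8, byrow = TRUE, dimnames = list(labs, labs))
  m
})

# Group-average driving-input weights per left-hemisphere area.
DRIVING_INPUT_TABLE <- c(M1_L = 1.26, SMA_L = 0.1, PMd_L = 0.04, PMv_L = 0.08)

#' Age slope reaching a target coefficient of determination
#'
#' For couplings modelled as intercept + slope * (age - ref) + noise with
#' ages uniform on `[age_low, age_high]`, returns the slope for which the
#' population r-squared of the coupling-age regression equals `r2`:
#' slope = sqrt(r2 / (1 - r2)) * resid_sd / sd(age).
#'
#' @param r2 target coefficient of determination, in (0, 1).
#' @param resid_sd residual standard deviation of the coupling (1/s).
#' @param age_low,age_high age range in years.
#' @return slope in 1/s per year.
#' @export
calibrate_slope <- function(r2, resid_sd, age_low = 19, age_high = 77) {
  stopifnot(r2 > 0, r2 < 1, resid_sd > 0, age_high > age_low)
  sd_age <- (age_high - age_low) / sqrt(12)
  sqrt(r2 / (1 - r2)) * resid_sd / sd_age
}

#' Age-effect specification for the synthetic cohort
#'
#' Describes, per connection, a linear age model for the intrinsic coupling
#' (value at the reference age, slope per year, residual sd, and a pattern
#' label), the force-modulation (B) effects of the generating model, the
#' driving-input weights, and the TMS linkage through which the change in
#' interhemispheric inhibition tracks the left-to-right M1 coupling.
#' Pattern `type1` connections cross zero within the age range (inhibitory
#' when young, facilitatory when old); `type2` connections are facilitatory
#' throughout and strengthen with age; `none` connections have no age
#' trend.
#'
#' @param connections data.frame with columns `from`, `to`, `intercept`
#'   (coupling at the reference age, 1/s), `slope` (1/s per year),
#'   `resid_sd` (1/s), `pattern` (`type1`/`type2`/`none`).
#' @param b_effects data.frame with columns `from`, `to`, `value`,
#'   `age_slope`, `resid_sd` for the modulatory entries of the generating
#'   model (self entries use `from == to`).
#' @param c_values named vector of driving weights per input region.
#' @param ihi list with `linkage` (change-IHI units per 1/s of coupling),
#'   `mep_sdlog` (lognormal trial variability), `rest_ihi`, `n_trials`,
#'   `test_mean` (mV).
#' @param age_ref reference age in years (defaults to the cohort midpoint).
#' @return An `effect_spec` object.
#' @seealso [default_effect_spec()]
#' @export
effect_spec <- function(connections, b_effects, c_values, ihi,
                        age_ref = 48) {
  need <- c("from", "to", "intercept", "slope", "resid_sd", "pattern")
  if (!all(need %in% names(connections))) {
    stop("connections must have columns ", paste(need, collapse = ", "))
  }
  if (!all(connections$pattern %in% c("type1", "type2", "none"))) {
    stop("pattern labels must be type1, type2 or none")
  }
  structure(list(connections = connections, b_effects = b_effects,
                 c_values = c_values, ihi = ihi, age_ref = age_ref),
            class = "effect_spec")
}

#' Default age effects calibrated to the hand-grip study
#'
#' Builds the generator's standard effect specification for a region set:
#' baseline couplings from the group-average grip connectivity table;
#' type 1 patterns (inhibition releasing with age) on every connection
#' targeting right M1, with the left-to-right M1 slope calibrated to
#' r-squared 0.64 and the others to 0.30; type 2 patterns (increasing
#' facilitation) on right-hemisphere intrahemispheric connections between
#' secondary areas, with slopes bounded to keep the mean line positive
#' across the age range; force modulation on the winning-family maximal
#' model (left M1 to each contralateral secondary area) with weight -0.75
#' per unit MVC-fraction deviation: with the impulse-coded force covariate
#' this makes the modulated per-event transfer roughly a third of the
#' intrinsic transfer, the reported size of the force effect; it drifts
#' more negative with age; driving weights from the group-average input table;
#' and a TMS linkage calibrated so change-IHI vs age recovers r-squared
#' around 0.45.
#'
#' @param regions a [region_set()] whose labels are a subset of the default
#'   eight-region network.
#' @param age_low,age_high cohort age range in years.
#' @return An [effect_spec()] object.
#' @export
default_effect_spec <- function(regions = region_set(), age_low = 19,
                                age_high = 77) {
  labs <- regions$labels
  if (!all(labs %in% rownames(GRIP_COUPLING_TABLE))) {
    stop("default effects are defined for the standard motor region labels")
  }
  age_ref <- (age_low + age_high) / 2
  base <- GRIP_COUPLING_TABLE[labs, labs]
  cons <- expand.grid(to = labs, from = labs, stringsAsFactors = FALSE)
  cons <- cons[cons$to != cons$from, c("from", "to")]
  cons$intercept <- base[cbind(cons$to, cons$from)]
  cons$slope <- 0
  cons$resid_sd <- 0.05
  cons$pattern <- "none"

  into_rm1 <- cons$to == "M1_R"
  cons$pattern[into_rm1] <- "type1"
  cons$slope[into_rm1] <- calibrate_slope(0.30, 0.05, age_low, age_high)
  lm1_rm1 <- cons$from == "M1_L" & cons$to == "M1_R"
  cons$slope[lm1_rm1] <- calibrate_slope(0.64, 0.05, age_low, age_high)

  rh_sec <- labs[regions$hemisphere == "R" & regions$area != "M1"]
  t2 <- cons$from %in% rh_sec & cons$to %in% rh_sec
  if (any(t2)) {
    cons$pattern[t2] <- "type2"
    cons$resid_sd[t2] <- 0.01
    cons$intercept[t2] <- pmax(cons$intercept[t2], 0.03)
    cons$slope[t2] <- 0.5 * cons$intercept[t2] / (age_high - age_ref)
  }

  sec_targets <- rh_sec
  b_inter <- data.frame(from = "M1_L", to = sec_targets,
                        value = -0.75,
                        age_slope = -calibrate_slope(0.2, 0.1, age_low, age_high),
                        resid_sd = 0.1)
  b_self <- data.frame(from = c("M1_L", sec_targets),
                       to = c("M1_L", sec_targets),
                       value = -0.02, age_slope = 0, resid_sd = 0.01)
  effect_spec(connections = cons, b_effects = rbind(b_inter, b_self),
              c_values = DRIVING_INPUT_TABLE[intersect(names(DRIVING_INPUT_TABLE), labs)],
              ihi = list(linkage = 3, mep_sdlog = 0.25, rest_ihi = 0.575,
                         n_trials = 10, test_mean = 1.25),
              age_ref = age_ref)
}

#' Null-effect specification
#'
#' The same baseline network as [default_effect_spec()] but with every age
#' slope, pattern label and TMS linkage set to zero: couplings carry only
#' subject-level residual variation, so no systematic age relationship
#' exists anywhere.
#'
#' @inheritParams default_effect_spec
#' @return An [effect_spec()] object.
#' @export
null_effect_spec <- function(regions = region_set(), age_low = 19,
                             age_high = 77) {
  eff <- default_effect_spec(regions, age_low, age_high)
  eff$connections$slope <- 0
  eff$connections$pattern <- "none"
  eff$b_effects$age_slope <- 0
  eff$ihi$linkage <- 0
  eff
}

#' Simulate paired-pulse MEP trials for one subject and condition
#'
#' Test amplitudes are lognormal around the calibrated 1.25 mV target;
#' conditioned amplitudes are scaled so the expected conditioned/test ratio
#' equals the resting IHI baseline at rest and, in the active condition,
#' the baseline times `1 + linkage * coupling` (truncated positive), so the
#' expected task-related change in IHI is exactly `1 + linkage * coupling`.
#'
#' @param coupling the subject's left-to-right M1 coupling (1/s).
#' @param condition `"rest"` or `"active"`.
#' @param n_trials trials per type (default 10).
#' @param linkage change-IHI units per unit coupling.
#' @param noise_sd lognormal sigma of trial amplitudes (0 = deterministic).
#' @param seed integer seed.
#' @param rest_ihi resting conditioned/test ratio baseline.
#' @param test_mean expected test MEP amplitude (mV).
#' @return A [mep_set()].
#' @export
mep_simulator <- function(coupling, condition = c("rest", "active"),
                          n_trials = 10, linkage = 3, noise_sd = 0.25,
                          seed = 1, rest_ihi = 0.575, test_mean = 1.25) {
  condition <- match.arg(condition)
  if (n_trials < 1) stop("n_trials must be >= 1")
  ratio <- if (condition == "rest") rest_ihi else {
    rest_ihi * max(1 + linkage * coupling, 1e-6)
  }
  with_seed(seed, {
    if (noise_sd > 0) {
      mulog <- -noise_sd^2 / 2  # E[lognormal] correction
      test <- rlnorm(n_trials, log(test_mean) + mulog, noise_sd)
      cond <- rlnorm(n_trials, log(test_mean * ratio) + mulog, noise_sd)
    } else {
      test <- rep(test_mean, n_trials)
      cond <- rep(test_mean * ratio, n_trials)
    }
    mep_set(test, cond, condition = condition)
  })
}

#' Generate a synthetic study cohort
#'
#' Draws subjects with ages, builds each subject's ground-truth coupling
#' matrices from the effect specification (linear age models plus Gaussian
#' residuals; modulation and driving input from the winning-family maximal
#' model), simulates a full BOLD session through the haemodynamic forward
#' model with noise set by the target signal-to-noise ratio, and simulates
#' resting and active paired-pulse MEP trials whose change in IHI tracks
#' the left-to-right M1 coupling. Bit-for-bit reproducible given `seed`.
#'
#' @param n number of subjects (>= 2).
#' @param age_low,age_high age range in years.
#' @param effects an [effect_spec()]; defaults to
#'   [default_effect_spec()] for `regions`.
#' @param regions a [region_set()].
#' @param snr per-subject signal-to-noise ratio (signal sd / noise sd) used
#'   when `noise_sd` is NULL.
#' @param noise_sd fixed BOLD noise sd (percent units), overriding `snr`.
#' @param seed master integer seed.
#' @param age_dist `"uniform"` (default) or `"normal"` (truncated normal
#'   with the study's mean 41.8 and sd 19.1).
#' @param paradigm_args list of arguments for [build_paradigm()].
#' @param baseline constant added to the stored BOLD series (default 100,
#'   emulating grand-mean-scaled units).
#' @param simulate generate BOLD sessions (default TRUE); with FALSE only
#'   ages, ground-truth parameters and MEP trials are produced, which is
#'   enough for statistical checks of the generator itself.
#' @return A `synthetic_cohort`: list with `subjects` (each holding `id`,
#'   `age`, `truth` ([dcm_params()]), `bold`, `meps`, `change_ihi`, `seed`),
#'   `effects`, `regions`, `paradigm`, `seed`.
#' @export
sample_cohort <- function(n = 27, age_low = 19, age_high = 77,
                          effects = NULL, regions = region_set(), snr = 1,
                          noise_sd = NULL, seed = 1,
                          age_dist = c("uniform", "normal"),
                          paradigm_args = list(), baseline = 100,
                          simulate = TRUE) {
  if (n < 2) stop("need at least two subjects")
  if (age_high <= age_low) stop("age_high must exceed age_low")
  age_dist <- match.arg(age_dist)
  if (is.null(effects)) effects <- default_effect_spec(regions, age_low, age_high)
  validate_effects(effects, age_low, age_high)
  labs <- regions$labels
  nreg <- regions$n

  ages <- with_seed(sub_seed(seed, 0), {
    if (age_dist == "uniform") runif(n, age_low, age_high) else {
      a <- rnorm(2 * n, 41.8, 19.1)
      a <- a[a >= age_low & a <= age_high]
      while (length(a) < n) a <- c(a, pmin(pmax(rnorm(n, 41.8, 19.1), age_low), age_high))
      a[seq_len(n)]
    }
  })

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    s_i <- sub_seed(seed, i)
    age <- ages[i]
    da <- age - effects$age_ref

    A <- matrix(0, nreg, nreg, dimnames = list(labs, labs))
    diag(A) <- -0.5
    cons <- effects$connections
    resid <- with_seed(s_i, rnorm(nrow(cons), 0, cons$resid_sd))
    A[cbind(cons$to, cons$from)] <- cons$intercept + cons$slope * da + resid

    Bmod <- matrix(0, nreg, nreg, dimnames = list(labs, labs))
    be <- effects$b_effects
    bres <- with_seed(s_i + 1L, rnorm(nrow(be), 0, be$resid_sd))
    Bmod[cbind(be$to, be$from)] <- be$value + be$age_slope * da + bres

    C <- matrix(0, nreg, 2, dimnames = list(labs, c("driving", "modulatory")))
    C[names(effects$c_values), 1] <- effects$c_values

    truth <- dcm_params(A, list(matrix(0, nreg, nreg), Bmod), C)
    paradigm <- do.call(build_paradigm,
                        c(paradigm_args, list(seed = sub_seed(s_i, 2))))
    bold <- NULL
    if (simulate) {
      inputs <- build_inputs(paradigm)
      clean <- simulate_bold(truth, paradigm = paradigm, noise_sd = 0,
                             inputs = inputs, baseline = 0)
      sig_sd <- sd(sweep(clean$y, 2, colMeans(clean$y)))
      nsd <- if (is.null(noise_sd)) sig_sd / snr else noise_sd
      noise <- with_seed(sub_seed(s_i, 3),
                         matrix(rnorm(length(clean$y), 0, nsd), nrow(clean$y)))
      bold <- clean
      bold$y <- clean$y + baseline + noise
      bold$meta <- list(noise_sd = nsd, snr = snr, seed = s_i,
                        baseline = baseline, scale = 100)
    }

    coupling <- A["M1_R", "M1_L"]
    meps <- list(
      rest = mep_simulator(coupling, "rest",
                           n_trials = effects$ihi$n_trials,
                           linkage = effects$ihi$linkage,
                           noise_sd = effects$ihi$mep_sdlog,
                           seed = sub_seed(s_i, 4),
                           rest_ihi = effects$ihi$rest_ihi,
                           test_mean = effects$ihi$test_mean),
      active = mep_simulator(coupling, "active",
                             n_trials = effects$ihi$n_trials,
                             linkage = effects$ihi$linkage,
                             noise_sd = effects$ihi$mep_sdlog,
                             seed = sub_seed(s_i, 5),
                             rest_ihi = effects$ihi$rest_ihi,
                             test_mean = effects$ihi$test_mean))
    subjects[[i]] <- structure(
      list(id = i, age = age, truth = truth, bold = bold, meps = meps,
           paradigm = paradigm,
           change_ihi = change_ihi(ihi(meps$active), ihi(meps$rest)),
           seed = s_i),
      class = "synthetic_subject")
  }
  structure(list(subjects = subjects, effects = effects, regions = regions,
                 seed = seed, snr = snr,
                 ages = vapply(subjects, function(s) s$age, numeric(1))),
            class = "synthetic_cohort")
}

validate_effects <- function(effects, age_low, age_high) {
  cons <- effects$connections
  ref <- effects$age_ref
  lo <- cons$intercept + cons$slope * (age_low - ref)
  hi <- cons$intercept + cons$slope * (age_high - ref)
  t1 <- cons$pattern == "type1"
  if (any(t1 & !(lo < 0 & hi > 0))) {
    bad <- which(t1 & !(lo < 0 & hi > 0))[1]
    stop(sprintf(
      "configuration error: type1 connection %s->%s does not cross zero within the age range",
      cons$from[bad], cons$to[bad]))
  }
  t2 <- cons$pattern == "type2"
  if (any(t2 & !(lo > 0 & cons$slope > 0))) {
    bad <- which(t2 & !(lo > 0 & cons$slope > 0))[1]
    stop(sprintf(
      "configuration error: type2 connection %s->%s must stay positive and increase",
      cons$from[bad], cons$to[bad]))
  }
  invisible(TRUE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, ages %.0f-%.0f, %d regions, seed %d\n",
              length(x$subjects), min(x$ages), max(x$ages), x$regions$n,
              x$seed))
  invisible(x)
}

#' Per-subject ground-truth coupling of one connection
#'
#' @param cohort a [sample_cohort()] object.
#' @param from,to region labels of the connection.
#' @return numeric vector across subjects.
#' @export
cohort_truth <- function(cohort, from = "M1_L", to = "M1_R") {
  vapply(cohort$subjects, function(s) s$truth$A[to, from], numeric(1))
}

#' Write a cohort to plain-text artifacts
#'
#' Writes per-subject BOLD TSV, MEP trial TSV, ground-truth JSON and a
#' manifest JSON to a directory.
#'
#' @param cohort a [sample_cohort()] object.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cohort$seed, regions = cohort$regions$labels,
                   subjects = list())
  for (s in cohort$subjects) {
    bold_path <- file.path(dir, sprintf("sub%02d_bold.tsv", s$id))
    mep_path <- file.path(dir, sprintf("sub%02d_mep.tsv", s$id))
    truth_path <- file.path(dir, sprintf("sub%02d_truth.json", s$id))
    write_timeseries(s$bold, bold_path)
    write_mep_trials(lapply(s$meps, function(mp) {
      mp$subject <- s$id
      mp
    }), mep_path)
    jsonlite::write_json(list(A = s$truth$A, B = s$truth$B, C = s$truth$C,
                              age = s$age, seed = s$seed),
                         truth_path, digits = NA, matrix = "rowmajor")
    manifest$subjects[[length(manifest$subjects) + 1]] <-
      list(id = s$id, age = s$age, bold = basename(bold_path),
           mep = basename(mep_path), truth = basename(truth_path))
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
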