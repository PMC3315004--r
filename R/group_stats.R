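#' Linear correlation between two subject-level measures
#'
#' Pearson correlation with the squared coefficient (r-squared), a
#' two-sided p-value from the t distribution with n - 2 degrees of
#' freedom, and the least-squares line.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @return A `correlation_result`: list with `r2`, `r`, `p`, `slope`,
#'   `intercept`, `n`.
#' @examples
#' correlate(c(1, 2, 3), c(1, 2, 4))$r2  # 27/28
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least three observations")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  slope <- r * sd(y) / sd(x)
  structure(list(r2 = r^2, r = r, p = p, slope = slope,
                 intercept = mean(y) - slope * mean(x), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r2 = %.3f, p = %.4g, slope = %.4g (n = %d)\n",
              x$r2, x$p, x$slope, x$n))
  invisible(x)
}

#' Classify the age pattern of a coupling parameter
#'
#' Two patterns of age-related change in intrinsic coupling are
#' distinguished, both requiring a significant positive age trend
#' (two-sided p < `p_threshold` on the slope): `type1`, a release of
#' inhibition, where the youngest age tertile has a negative mean coupling
#' and the oldest a positive one; and `type2`, increasing facilitation,
#' where couplings are positive in all but at most `max_negative`
#' subjects. Anything else is `none`. Tertile boundaries use the empirical
#' 33/67 age percentiles.
#'
#' @param couplings per-subject coupling values (1/s).
#' @param ages per-subject ages (years); n >= 6.
#' @param p_threshold significance threshold on the slope (default 0.05).
#' @param max_negative maximum negative subjects tolerated for type2
#'   (default 3).
#' @return `"type1"`, `"type2"` or `"none"`.
#' @export
classify_pattern <- function(couplings, ages, p_threshold = 0.05,
                             max_negative = 3) {
  if (length(couplings) != length(ages)) stop("lengths differ")
  if (length(ages) < 6) stop("need at least six subjects to classify")
  cr <- correlate(ages, couplings)
  if (!(cr$slope > 0 && cr$p < p_threshold)) return("none")
  qs <- quantile(ages, c(1 / 3, 2 / 3), names = FALSE)
  young <- couplings[ages <= qs[1]]
  old <- couplings[ages >= qs[2]]
  if (mean(young) < 0 && mean(old) > 0) return("type1")
  if (sum(couplings < 0) <= max_negative) return("type2")
  "none"
}

#' Permutation null for a correlation
#'
#' Distribution of r-squared under random re-pairing of `x` and `y`
#' (shuffling the labels of `x`). Deterministic given `seed`.
#'
#' @param x,y numeric vectors.
#' @param n_perm number of shuffles (default 1000).
#' @param seed integer seed.
#' @return numeric vector of `n_perm` r-squared values.
#' @export
permutation_null_r2 <- function(x, y, n_perm = 1000, seed = 1) {
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) correlate(sample(x), y)$r2,
           numeric(1))
  })
}

#' Read a pipeline configuration from YAML
#'
#' Maps a flat YAML file onto the [run_pipeline()] configuration list.
#' Recognised keys: `n`, `seed`, `age_low`, `age_high`, `snr`, `n_perm`,
#' `families` (`winning`/`all`), `network` (`reduced`/`full`) and
#' `effects` (`default`/`null`).
#'
#' @param path YAML file path. Note YAML 1.1 treats a bare `n` key as a
#'   boolean; write it quoted (`"n": 12`) or rely on the normalisation
#'   applied here.
#' @return configuration list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  cfg <- yaml::read_yaml(path)
  # a bare `n:` key arrives as the boolean FALSE under YAML 1.1
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  if (!is.null(cfg$network)) {
    cfg$regions <- switch(match.arg(cfg$network, c("reduced", "full")),
                          reduced = reduced_region_set(),
                          full = region_set())
    cfg$network <- NULL
  }
  if (!is.null(cfg$effects) && is.character(cfg$effects)) {
    regions <- if (is.null(cfg$regions)) reduced_region_set() else cfg$regions
    lo <- if (is.null(cfg$age_low)) 19 else cfg$age_low
    hi <- if (is.null(cfg$age_high)) 77 else cfg$age_high
    cfg$effects <- switch(match.arg(cfg$effects, c("default", "null")),
                          default = default_effect_spec(regions, lo, hi),
                          null = null_effect_spec(regions, lo, hi))
  }
  cfg
}

#' Run the full synthetic analysis chain
#'
#' Orchestrates the study pipeline on a synthetic cohort: generate (or
#' accept) the cohort, enumerate the model space, invert the winning-family
#' members for every subject, average their parameters by model evidence
#' (BMA), correlate each intrinsic coupling with age, classify its age
#' pattern, and relate the left-to-right M1 coupling to the TMS change in
#' interhemispheric inhibition. Deterministic given the seed inside
#' `config`.
#'
#' @param config list of settings; recognised entries (all optional):
#'   `regions` (a [region_set()], default [reduced_region_set()] to keep a
#'   full run at desk scale), `n` subjects (default 12), `age_low`,
#'   `age_high`, `effects` (default [default_effect_spec()] for the
#'   regions; use [null_effect_spec()] for a null run), `snr`, `seed`,
#'   `families` (`"winning"` default, or `"all"` to invert the whole space
#'   and run FFX/RFX family comparison first), `priors`, `settings`
#'   (inversion settings), `n_perm` permutation shuffles (default 1000; 0
#'   disables), `cohort` (a pre-built [sample_cohort()], overriding the
#'   generator entries), `out_dir` (write report JSON and tables there).
#' @return A `pipeline_report`: list with `winning_family`,
#'   `family_comparison` (NULL unless `families = "all"`), `bma` (subjects
#'   x parameters matrix), `age_correlations` (data.frame per connection:
#'   r2, p, slope, pattern), `ihi_correlation`
#'   (left-to-right M1 coupling vs change-IHI), `perm_null_q95`, `ages`,
#'   `change_ihi`, `config_echo`, `seeds`, `n_tests`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    regions = reduced_region_set(), n = 12, age_low = 19, age_high = 77,
    effects = NULL, snr = 1, seed = 1, families = "winning", priors = prior_spec(),
    settings = inversion_settings(), n_perm = 1000, cohort = NULL,
    out_dir = NULL), config)

  cohort <- cfg$cohort
  if (is.null(cohort)) {
    cohort <- sample_cohort(n = cfg$n, age_low = cfg$age_low,
                            age_high = cfg$age_high, effects = cfg$effects,
                            regions = cfg$regions, snr = cfg$snr,
                            seed = cfg$seed)
  }
  regions <- cohort$regions
  space <- enumerate_model_space(regions)
  win <- winning_family_models(space)
  fam_cmp <- NULL
  models_to_fit <- win
  if (identical(cfg$families, "all")) models_to_fit <- space$models

  fits <- lapply(cohort$subjects, function(subj) {
    ts <- preprocess_ts(subj$bold)
    inputs <- build_inputs(subj$paradigm)
    lapply(models_to_fit, function(mod) {
      invert_model(ts, inputs, mod, priors = cfg$priors,
                   settings = cfg$settings)
    })
  })

  if (identical(cfg$families, "all")) {
    ev <- t(vapply(fits, function(fr) {
      vapply(fr, function(f) f$free_energy, numeric(1))
    }, numeric(length(models_to_fit))))
    colnames(ev) <- vapply(models_to_fit, function(mod) {
      as.character(mod$model_id)
    }, character(1))
    fam_map <- vapply(models_to_fit, function(mod) mod$family_id, integer(1))
    ffx <- ffx_group(ev, fam_map)
    rfx <- rfx_family(ev, fam_map, seed = sub_seed(cfg$seed, 97))
    fam_cmp <- list(ffx = ffx, rfx = rfx,
                    winning_family = as.integer(names(which.max(
                      ffx$family_log_evidence))))
    win_ids <- vapply(win, function(mod) mod$model_id, integer(1))
    keep <- which(vapply(models_to_fit, function(mod) {
      mod$model_id %in% win_ids
    }, logical(1)))
    fits <- lapply(fits, function(fr) fr[keep])
  }

  bma <- lapply(fits, bma_subject)
  pnames <- names(bma[[1]]$params)
  bma_mat <- t(vapply(bma, function(b) b$params[pnames],
                      numeric(length(pnames))))
  colnames(bma_mat) <- pnames

  ages <- cohort$ages
  chihi <- vapply(cohort$subjects, function(s) s$change_ihi, numeric(1))

  labs <- regions$labels
  a_cols <- grep("^A\\[", pnames, value = TRUE)
  age_cor <- do.call(rbind, lapply(a_cols, function(cn) {
    vals <- bma_mat[, cn]
    cr <- correlate(ages, vals)
    data.frame(connection = cn, r2 = cr$r2, p = cr$p, slope = cr$slope,
               pattern = classify_pattern(vals, ages))
  }))

  lm1_rm1 <- sprintf("A[%s,%s]", "M1_R", "M1_L")
  ihi_cor <- correlate(chihi, bma_mat[, lm1_rm1])
  q95 <- NULL
  if (cfg$n_perm > 0) {
    null_r2 <- permutation_null_r2(ages, bma_mat[, lm1_rm1],
                                   n_perm = cfg$n_perm,
                                   seed = sub_seed(cfg$seed, 131))
    q95 <- quantile(null_r2, 0.95, names = FALSE)
  }

  report <- structure(list(
    winning_family = if (is.null(fam_cmp)) win[[1]]$family_id else
      fam_cmp$winning_family,
    family_comparison = fam_cmp,
    bma = bma_mat,
    age_correlations = age_cor,
    lm1_rm1_age = correlate(ages, bma_mat[, lm1_rm1]),
    ihi_correlation = ihi_cor,
    perm_null_q95 = q95,
    ages = ages, change_ihi = chihi,
    n_tests = nrow(age_cor),
    seeds = list(master = cfg$seed),
    config_echo = cfg[setdiff(names(cfg), c("cohort", "out_dir"))]),
    class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: winning family %d, %d subjects\n",
              x$winning_family, length(x$ages)))
  cat(sprintf("LM1->RM1 vs age: r2 = %.3f, p = %.4g, slope = %.4g\n",
              x$lm1_rm1_age$r2, x$lm1_rm1_age$p, x$lm1_rm1_age$slope))
  cat(sprintf("LM1->RM1 vs changeIHI: r2 = %.3f, p = %.4g\n",
              x$ihi_correlation$r2, x$ihi_correlation$p))
  pats <- x$age_correlations$pattern
  cat(sprintf("Patterns: %d type1, %d type2 of %d connections (no multiplicity correction)\n",
              sum(pats == "type1"), sum(pats == "type2"), length(pats)))
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$age_correlations, file.path(dir, "age_correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(age = report$ages, change_ihi = report$change_ihi,
                         report$bma, check.names = FALSE),
              file.path(dir, "bma_parameters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    winning_family = report$winning_family,
    lm1_rm1_age = unclass(report$lm1_rm1_age),
    ihi_correlation = unclass(report$ihi_correlation),
    perm_null_q95 = report$perm_null_q95,
    n_tests = report$n_tests,
    seeds = report$seeds), file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
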