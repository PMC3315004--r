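#' Paired-pulse TMS trial set
#'
#' Holds motor-evoked-potential (MEP) peak-to-peak amplitudes from single
#' (test) and paired-pulse (conditioning + test) trials for one subject in
#' one condition. The protocol uses ten trials of each type with the test
#' stimulus calibrated to evoke a 1-1.5 mV MEP.
#'
#' @param test_amplitudes test-trial MEP amplitudes (mV), positive.
#' @param conditioned_amplitudes paired-pulse MEP amplitudes (mV), positive.
#' @param condition `"rest"` or `"active"`.
#' @param subject optional subject identifier.
#' @return A `mep_set` object.
#' @export
mep_set <- function(test_amplitudes, conditioned_amplitudes,
                    condition = c("rest", "active"), subject = NA) {
  condition <- match.arg(condition)
  if (length(test_amplitudes) < 1 || length(conditioned_amplitudes) < 1) {
    stop("both trial lists must be non-empty")
  }
  if (any(test_amplitudes <= 0) || any(conditioned_amplitudes <= 0)) {
    stop("MEP amplitudes must be positive")
  }
  structure(list(test_amplitudes = as.numeric(test_amplitudes),
                 conditioned_amplitudes = as.numeric(conditioned_amplitudes),
                 condition = condition, subject = subject),
            class = "mep_set")
}

#' Interhemispheric inhibition from MEP trials
#'
#' IHI is the conditioned/test MEP amplitude ratio, aggregated as the ratio
#' of trial means (arithmetic mean of amplitudes per trial type, then the
#' ratio; `aggregate = "mean_of_ratios"` pairs trials index-wise instead).
#' Values below 1 reflect inhibition of the test response by the
#' conditioning pulse to the opposite hemisphere.
#'
#' @param meps a [mep_set()].
#' @param aggregate `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return An `ihi_value`: list with `value` and `condition`.
#' @examples
#' ihi(mep_set(c(1.0, 1.2, 0.8), c(0.6, 0.5, 0.7)))$value  # 0.6
#' @export
ihi <- function(meps, aggregate = c("ratio_of_means", "mean_of_ratios")) {
  aggregate <- match.arg(aggregate)
  mt <- mean(meps$test_amplitudes)
  if (mt == 0) stop("mean test amplitude is zero")
  value <- if (aggregate == "ratio_of_means") {
    mean(meps$conditioned_amplitudes) / mt
  } else {
    if (length(meps$conditioned_amplitudes) != length(meps$test_amplitudes)) {
      stop("mean_of_ratios needs paired trial lists of equal length")
    }
    mean(meps$conditioned_amplitudes / meps$test_amplitudes)
  }
  structure(list(value = value, condition = meps$condition),
            class = "ihi_value")
}

#' Task-related change in interhemispheric inhibition
#'
#' changeIHI = active IHI / rest IHI. Values below 1 indicate that the
#' task strengthens inhibition; above 1, that inhibition is released.
#'
#' @param active IHI in the active condition ([ihi()] result or number).
#' @param rest IHI at rest ([ihi()] result or number); must be positive.
#' @return dimensionless ratio.
#' @examples
#' change_ihi(0.5, 1.0)  # 0.5: the task strengthens inhibition
#' @export
change_ihi <- function(active, rest) {
  a <- if (inherits(active, "ihi_value")) active$value else active
  r <- if (inherits(rest, "ihi_value")) rest$value else rest
  if (r == 0) stop("rest IHI is zero")
  a / r
}

#' Read or write trial-level MEP tables
#'
#' Tab-delimited text with columns subject, condition, trial_type
#' (test|conditioned), amplitude_mV.
#'
#' @param meps_list list of [mep_set()] objects.
#' @param path file path.
#' @rdname mep_io
#' @export
write_mep_trials <- function(meps_list, path) {
  rows <- do.call(rbind, lapply(meps_list, function(mp) {
    rbind(data.frame(subject = mp$subject, condition = mp$condition,
                     trial_type = "test", amplitude_mV = mp$test_amplitudes),
          data.frame(subject = mp$subject, condition = mp$condition,
                     trial_type = "conditioned",
                     amplitude_mV = mp$conditioned_amplitudes))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname mep_io
#' @export
read_mep_trials <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  out <- list()
  for (subj in unique(tab$subject)) {
    for (cond in unique(tab$condition[tab$subject == subj])) {
      sel <- tab[tab$subject == subj & tab$condition == cond, ]
      out[[length(out) + 1]] <- mep_set(
        sel$amplitude_mV[sel$trial_type == "test"],
        sel$amplitude_mV[sel$trial_type == "conditioned"],
        condition = cond, subject = subj)
    }
  }
  out
}
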