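#' Fixed-effects group model and family comparison
#'
#' Under fixed-effects (FFX) inference the subjects share one model, so
#' group log evidence is the column sum of the subjects x models
#' log-evidence matrix and log Group Bayes Factors (GBF) are differences of
#' those sums. Family evidence per subject aggregates member models with a
#' uniform within-family prior (log-sum-exp of member log evidences minus
#' log family size, the default) or by plain summation (`method = "sum"`);
#' family posteriors assume a uniform prior over families. Both are
#' invariant to adding a constant to every subject's evidences.
#'
#' @param ev numeric subjects x models matrix of log evidences (nats);
#'   columns named by model id.
#' @param families integer vector mapping each column to a family id (e.g.
#'   [model_families()]); NULL for model-level output only.
#' @param method family aggregation: `"lse"` (log-sum-exp, default) or
#'   `"sum"`.
#' @return A list with `group_log_evidence` (per model), `log_gbf` (per
#'   model, relative to the best model), `model_posterior`,
#'   `family_log_evidence`, `family_posterior` (NULL without `families`).
#' @examples
#' ev <- rbind(c(0, 3), c(0, 3))  # two subjects favour model 2 by 3 nats
#' ffx_group(ev)$log_gbf          # c(-6, 0)
#' @export
ffx_group <- function(ev, families = NULL, method = c("lse", "sum")) {
  ev <- as.matrix(ev)
  if (length(ev) == 0 || nrow(ev) < 1) stop("evidence matrix is empty")
  if (!all(is.finite(ev))) stop("evidence matrix must be finite")
  method <- match.arg(method)
  group <- colSums(ev)
  log_gbf <- group - max(group)
  model_post <- exp(log_gbf - log_sum_exp(log_gbf))
  fam_log <- fam_post <- NULL
  if (!is.null(families)) {
    if (length(families) != ncol(ev)) {
      stop("family mapping must cover every model column")
    }
    fam_ids <- sort(unique(families))
    per_subj <- sapply(fam_ids, function(fid) {
      cols <- which(families == fid)
      apply(ev[, cols, drop = FALSE], 1, function(row) {
        if (method == "lse") log_sum_exp(row) - log(length(cols)) else sum(row)
      })
    })
    per_subj <- matrix(per_subj, nrow = nrow(ev),
                       dimnames = list(NULL, fam_ids))
    fam_log <- colSums(per_subj)
    fam_post <- exp(fam_log - log_sum_exp(fam_log))
  }
  list(group_log_evidence = group, log_gbf = log_gbf,
       model_posterior = model_post, family_log_evidence = fam_log,
       family_posterior = fam_post)
}

#' Random-effects family inference
#'
#' Treats the family generating each subject's data as a random effect:
#' family frequencies r follow a Dirichlet prior (uniform by default) and
#' each subject's family assignment a categorical draw. A Gibbs sampler
#' alternates assignments and frequencies; family evidence per subject uses
#' a uniform within-family model prior (log-sum-exp minus log size).
#' Returns expected family probabilities and exceedance probabilities (the
#' posterior probability that a family is the most frequent), estimated by
#' argmax counts over the retained sweeps. Deterministic given `seed`.
#'
#' @param ev subjects x models log-evidence matrix (nats).
#' @param families integer vector mapping columns to family ids.
#' @param n_samples Gibbs sweeps retained (default 1e4).
#' @param burn_in discarded initial sweeps (default 1e3).
#' @param seed integer seed.
#' @param alpha0 Dirichlet prior weight per family (default 1).
#' @return A `family_posterior` object: list with `expected_probability`,
#'   `exceedance_probability`, `dirichlet_alpha` (posterior mean of the
#'   counts + prior), `families`.
#' @export
rfx_family <- function(ev, families, n_samples = 1e4, burn_in = 1e3,
                       seed = 1, alpha0 = 1) {
  ev <- as.matrix(ev)
  fam_ids <- sort(unique(families))
  K <- length(fam_ids)
  if (K < 2) stop("need at least two families")
  if (n_samples < 1000) {
    warning("fewer than 1000 Gibbs samples; exceedance estimates will be noisy")
  }
  S <- nrow(ev)
  # subject x family log evidence under uniform within-family model priors
  fle <- sapply(fam_ids, function(fid) {
    cols <- which(families == fid)
    apply(ev[, cols, drop = FALSE], 1, function(row) {
      log_sum_exp(row) - log(length(cols))
    })
  })
  fle <- matrix(fle, nrow = S)
  fle <- fle - apply(fle, 1, max)

  with_seed(seed, {
    r <- rep(1 / K, K)
    exp_r <- numeric(K)
    wins <- numeric(K)
    alpha_acc <- numeric(K)
    total <- burn_in + n_samples
    for (it in seq_len(total)) {
      logw <- sweep(fle, 2, log(r), `+`)
      w <- exp(logw - apply(logw, 1, max))
      w <- w / rowSums(w)
      z <- apply(w, 1, function(pr) sample.int(K, 1, prob = pr))
      counts <- tabulate(z, K)
      alpha <- alpha0 + counts
      g <- rgamma(K, shape = alpha, rate = 1)
      r <- g / sum(g)
      if (it > burn_in) {
        exp_r <- exp_r + r
        wins[which.max(r)] <- wins[which.max(r)] + 1
        alpha_acc <- alpha_acc + alpha
      }
    }
    exp_r <- exp_r / n_samples
    xp <- wins / sum(wins)
    structure(list(expected_probability = setNames(exp_r, fam_ids),
                   exceedance_probability = setNames(xp, fam_ids),
                   dirichlet_alpha = setNames(alpha_acc / n_samples, fam_ids),
                   families = fam_ids, n_samples = n_samples),
              class = "family_posterior")
  })
}

#' @export
print.family_posterior <- function(x, ...) {
  cat("RFX family inference\n")
  print(round(rbind(expected = x$expected_probability,
                    exceedance = x$exceedance_probability), 4))
  invisible(x)
}

#' Bayesian model averaging for one subject
#'
#' Averages posterior parameter means across models with weights
#' proportional to exp(F), computed stably as normalised
#' exp(F_k - max F). Parameters are matched by name across the union
#' structure; a parameter absent from a model contributes its prior mean
#' of zero.
#'
#' @param results list of `inversion_result` objects for one subject.
#' @param log_ev optional log evidences (defaults to each result's
#'   `free_energy`).
#' @return A `bma_result`: list with `params` (named averaged posterior
#'   means over the union structure), `weights`, `model_ids`.
#' @examples
#' # two models with equal evidence average arithmetically
#' @export
bma_subject <- function(results, log_ev = NULL) {
  if (length(results) < 1) stop("need at least one inversion result")
  if (is.null(log_ev)) {
    log_ev <- vapply(results, function(r) r$free_energy, numeric(1))
  }
  if (length(log_ev) != length(results)) {
    stop("log_ev must match the number of results")
  }
  w <- exp(log_ev - max(log_ev))
  w <- w / sum(w)
  union_names <- unique(unlist(lapply(results, function(r) {
    names(r$posterior_mean)
  })))
  avg <- setNames(numeric(length(union_names)), union_names)
  for (k in seq_along(results)) {
    mk <- results[[k]]$posterior_mean
    avg[names(mk)] <- avg[names(mk)] + w[k] * mk
  }
  structure(list(params = avg, weights = w,
                 model_ids = vapply(results, function(r) {
                   if (is.null(r$model_id)) NA_integer_ else as.integer(r$model_id)
                 }, integer(1))),
            class = "bma_result")
}

#' Evidence-matrix I/O
#'
#' Tab-delimited tables, rows = subjects, columns = model ids.
#'
#' @param ev subjects x models matrix.
#' @param path file path.
#' @rdname evidence_io
#' @export
write_evidence <- function(ev, path) {
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname evidence_io
#' @export
read_evidence <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t", check.names = FALSE))
}
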