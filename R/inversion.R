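#' Shrinkage priors for DCM inversion
#'
#' Gaussian priors over the coupling parameters and a Gamma hyperprior over
#' the observation-noise precision. Defaults keep the system stable a
#' priori: intrinsic off-diagonal couplings ~ N(0, 1/64) per second,
#' self-connection log-scales ~ N(0, 1/256) (self-connections are
#' parameterised as -0.5*exp(theta), so theta = 0 means -0.5/s), modulatory
#' and driving entries ~ N(0, 1). Priors are identical across subjects.
#'
#' @param a_var prior variance of A off-diagonal entries (1/s)^2.
#' @param self_var prior variance of self-connection log-scales.
#' @param b_var prior variance of allowed B entries.
#' @param c_var prior variance of allowed C entries.
#' @param noise_shape,noise_rate shape and rate of the Gamma hyperprior on
#'   the noise precision; the default Gamma(1, 1/100) has prior mean
#'   precision 100 (noise sd 0.1 in percent-signal units) and is weak: one
#'   pseudo-observation against hundreds of volumes.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(a_var = 1 / 64, self_var = 1 / 256, b_var = 1,
                       c_var = 1, noise_shape = 1, noise_rate = 0.01) {
  vars <- c(a_var, self_var, b_var, c_var)
  if (any(vars <= 0)) stop("prior variances must be positive")
  if (noise_shape <= 0 || noise_rate <= 0) stop("noise hyperprior must be positive")
  structure(list(a_var = a_var, self_var = self_var, b_var = b_var,
                 c_var = c_var, noise_shape = noise_shape,
                 noise_rate = noise_rate),
            class = "prior_spec")
}

#' Inversion settings
#'
#' @param max_iter maximum Gauss-Newton iterations (default 128).
#' @param tol free-energy convergence tolerance in nats (default 0.01).
#' @param tol_streak successive sub-tolerance improvements required
#'   (default 3).
#' @param haemo a [haemo_params()] object (fixed during inversion).
#' @param scale output scale of the forward model (percent units).
#' @param init_jitter_sd sd of optional Gaussian jitter on the starting
#'   point (default 0: deterministic start at the prior mean).
#' @param seed seed for the initialization jitter.
#' @param init optional named numeric vector of starting values (matched to
#'   parameter names; unmatched parameters start at the prior mean).
#' @param verbose print the free-energy trace while optimising.
#' @return An `inversion_settings` object.
#' @export
inversion_settings <- function(max_iter = 128, tol = 0.01, tol_streak = 3,
                               haemo = haemo_params(), scale = 100,
                               init_jitter_sd = 0, seed = 1, init = NULL,
                               verbose = FALSE) {
  structure(list(max_iter = max_iter, tol = tol, tol_streak = tol_streak,
                 haemo = haemo, scale = scale,
                 init_jitter_sd = init_jitter_sd, seed = seed, init = init,
                 verbose = verbose),
            class = "inversion_settings")
}

# Parameter table for a model spec: one row per free parameter, with the
# 0-based (code, i, j, ch) encoding used by the C++ sensitivity kernel.
param_table <- function(spec, priors = prior_spec()) {
  labels <- rownames(spec$a_mask)
  n <- nrow(spec$a_mask)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && spec$a_mask[i, j] == 1) {
      rows[[length(rows) + 1]] <- data.frame(
        name = sprintf("A[%s,%s]", labels[i], labels[j]),
        code = 0L, i = i - 1L, j = j - 1L, ch = 0L, var = priors$a_var)
    }
  }
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <- data.frame(
      name = sprintf("self[%s]", labels[i]),
      code = 1L, i = i - 1L, j = i - 1L, ch = 0L, var = priors$self_var)
  }
  for (ch in seq_along(spec$b_masks)) {
    bm <- spec$b_masks[[ch]]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (bm[i, j] == 1) {
        rows[[length(rows) + 1]] <- data.frame(
          name = sprintf("B%d[%s,%s]", ch, labels[i], labels[j]),
          code = 2L, i = i - 1L, j = j - 1L, ch = ch - 1L, var = priors$b_var)
      }
    }
  }
  for (i in seq_len(n)) for (ch in seq_len(ncol(spec$c_mask))) {
    if (spec$c_mask[i, ch] == 1) {
      rows[[length(rows) + 1]] <- data.frame(
        name = sprintf("C[%s,%s]", labels[i], colnames(spec$c_mask)[ch]),
        code = 3L, i = i - 1L, j = 0L, ch = ch - 1L, var = priors$c_var)
    }
  }
  do.call(rbind, rows)
}

# Build (A, B, C) matrices from a parameter vector and its table.
theta_to_params <- function(theta, ptab, n, m, labels) {
  A <- matrix(0, n, n, dimnames = list(labels, labels))
  diag(A) <- -0.5
  B <- replicate(m, matrix(0, n, n, dimnames = list(labels, labels)),
                 simplify = FALSE)
  C <- matrix(0, n, m, dimnames = list(labels, NULL))
  for (k in seq_len(nrow(ptab))) {
    i <- ptab$i[k] + 1L; j <- ptab$j[k] + 1L; ch <- ptab$ch[k] + 1L
    switch(ptab$code[k] + 1L,
           A[i, j] <- theta[k],                    # A off-diagonal
           A[i, i] <- -0.5 * exp(theta[k]),        # self log-scale
           B[[ch]][i, j] <- theta[k],
           C[i, ch] <- theta[k])
  }
  dcm_params(A, B, C)
}

# Centre a stacked vector / Jacobian per region block (removes the unknown
# baseline of each region's series). For a (T*n) x p matrix the reshape to
# T x (n*p) makes every region block of every column a column of its own.
centre_blocks <- function(v, T_, n) {
  dims <- dim(v)
  k <- length(v) %/% T_
  dim(v) <- c(T_, k)
  v <- v - rep(.colMeans(v, T_, k), each = T_)
  dim(v) <- dims
  v
}

#' Gaussian expected log-likelihood (accuracy term)
#'
#' Accuracy component of the variational free energy under i.i.d. Gaussian
#' noise with precision `lambda`:
#' -N/2 log(2*pi) + N/2 log(lambda) - lambda/2 (r'r + trace_term),
#' where the trace term tr(J Sigma J') accounts for posterior uncertainty.
#'
#' @param resid residual vector.
#' @param lambda noise precision.
#' @param trace_term tr(J Sigma J') (default 0).
#' @return accuracy in nats.
#' @export
gaussian_accuracy <- function(resid, lambda, trace_term = 0) {
  N <- length(resid)
  -N / 2 * log(2 * pi) + N / 2 * log(lambda) -
    lambda / 2 * (sum(resid^2) + trace_term)
}

#' Kullback-Leibler divergence between two Gaussians
#'
#' KL(N(mu, Sigma) || N(mu0, Sigma0)); the complexity component of the
#' free energy. Zero when posterior equals prior.
#'
#' @param mu,Sigma posterior mean and covariance.
#' @param mu0,Sigma0 prior mean and covariance.
#' @return KL divergence in nats.
#' @export
kl_gaussian <- function(mu, Sigma, mu0, Sigma0) {
  p <- length(mu)
  ch0 <- chol(Sigma0)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) stop("posterior covariance is not positive definite")
  P0 <- chol2inv(ch0)
  d <- mu - mu0
  0.5 * (sum(P0 * Sigma) + sum(d * (P0 %*% d)) - p +
           2 * sum(log(diag(ch0))) - 2 * sum(log(diag(ch))))
}

#' Variational free energy from its components
#'
#' F = accuracy - complexity: the evidence lower bound balancing fit
#' against departure from the prior.
#'
#' @param accuracy expected log-likelihood (nats), e.g.
#'   [gaussian_accuracy()].
#' @param complexity KL(posterior || prior) (nats), e.g. [kl_gaussian()].
#' @return free energy in nats.
#' @export
free_energy <- function(accuracy, complexity) {
  accuracy - complexity
}

#' Invert one DCM on one subject's region time series
#'
#' Variational-Laplace estimation: a Gaussian posterior over the free
#' coupling parameters is optimised by Gauss-Newton ascent on the free
#' energy F = accuracy - complexity, with Levenberg-Marquardt damping.
#' Gradients use exact forward sensitivities of the neural states
#' propagated through the tangent-linearised haemodynamic stage. The
#' observation-noise precision is updated by EM under its Gamma hyperprior.
#' Parameters masked out by the model spec are not estimated (they are
#' pinned at the prior mean of zero). Each region's series is mean-centred
#' internally, so baselines are not modelled.
#'
#' Convergence is declared when |dF| stays below `tol` nats for
#' `tol_streak` successive iterations; hitting `max_iter` first returns a
#' result flagged `converged = FALSE` rather than an error.
#'
#' @param ts a `bold_timeseries` (T volumes x n regions).
#' @param inputs the matching [build_inputs()] object.
#' @param spec a `model_spec` from [enumerate_model_space()].
#' @param priors a [prior_spec()].
#' @param settings an [inversion_settings()].
#' @return An `inversion_result`: list with `posterior_mean` (named),
#'   `posterior_cov`, `free_energy`, `accuracy`, `complexity`, `lambda`,
#'   `n_iterations`, `converged`, `model_id`, `family_id`, `param_table`.
#' @export
invert_model <- function(ts, inputs, spec, priors = prior_spec(),
                         settings = inversion_settings()) {
  Y <- as.matrix(ts$y)
  n <- nrow(spec$a_mask)
  if (ncol(Y) != n) {
    stop(sprintf("time series has %d regions but the model spec has %d",
                 ncol(Y), n))
  }
  T_ <- nrow(Y)
  labels <- rownames(spec$a_mask)
  ptab <- param_table(spec, priors)
  p <- nrow(ptab)
  mu0 <- rep(0, p)
  prior_var <- ptab$var
  P0 <- diag(1 / prior_var, p)
  Sigma0 <- diag(prior_var, p)

  samp <- round((seq_len(T_) - 1) * ts$tr / inputs$dt)
  samp <- pmin(samp, ncol(inputs$u) - 1L)
  yv <- centre_blocks(as.numeric(Y), T_, n)
  N <- length(yv)
  a0 <- priors$noise_shape; b0 <- priors$noise_rate

  theta <- mu0
  if (!is.null(settings$init)) {
    hit <- match(ptab$name, names(settings$init))
    theta[!is.na(hit)] <- settings$init[hit[!is.na(hit)]]
  }
  if (settings$init_jitter_sd > 0) {
    theta <- theta + with_seed(settings$seed,
                               rnorm(p, 0, settings$init_jitter_sd))
  }
  pmat <- as.matrix(ptab[, c("code", "i", "j", "ch")])
  storage.mode(pmat) <- "integer"

  forward_pass <- function(theta) {
    par <- theta_to_params(theta, ptab, n, length(spec$b_masks), labels)
    fw <- cpp_dcm_forward_sens(par$A, b_cube(par), par$C, inputs$u,
                               inputs$dt, unclass(settings$haemo),
                               as.integer(samp), pmat, settings$scale)
    yhat <- centre_blocks(as.numeric(fw$y), T_, n)
    J <- centre_blocks(fw$J, T_, n)
    r <- yv - yhat
    list(r = r, J = J, JtJ = crossprod(J))
  }

  score <- function(fwd, theta, lambda) {
    H <- lambda * fwd$JtJ + P0
    Sigma <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    ridge <- FALSE
    while (is.null(Sigma)) {
      ridge <- TRUE
      H <- H + diag(mean(diag(H)) * 1e-6, p)
      Sigma <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    }
    if (ridge) warning("singular curvature; ridge-regularised posterior")
    trace_term <- sum(Sigma * fwd$JtJ)
    acc <- gaussian_accuracy(fwd$r, lambda, trace_term)
    cplx <- kl_gaussian(theta, Sigma, mu0, Sigma0)
    Fh <- a0 * log(b0) - lgamma(a0) + (a0 - 1) * log(lambda) - b0 * lambda
    c(fwd, list(F = free_energy(acc, cplx) + Fh, accuracy = acc,
                complexity = cplx, H = H, Sigma = Sigma,
                trace_term = trace_term))
  }

  evaluate <- function(theta, lambda) score(forward_pass(theta), theta, lambda)

  fwd0 <- forward_pass(theta)
  lambda <- (a0 + N / 2) / (b0 + 0.5 * sum(fwd0$r^2))
  cur <- score(fwd0, theta, lambda)
  lambda <- (a0 + N / 2) / (b0 + 0.5 * (sum(cur$r^2) + cur$trace_term))
  cur <- score(fwd0, theta, lambda)

  nu <- 1e-4
  streak <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < settings$max_iter) {
    iter <- iter + 1L
    g <- lambda * crossprod(cur$J, cur$r) - (theta - mu0) / prior_var
    improved <- FALSE
    for (try in 1:12) {
      Hd <- cur$H + diag(nu * diag(cur$H), p)
      step <- drop(solve(Hd, g))
      cand_theta <- theta + step
      cand_lambda <- (a0 + N / 2) /
        (b0 + 0.5 * (sum(cur$r^2) + cur$trace_term))
      cand <- tryCatch(evaluate(cand_theta, cand_lambda),
                       error = function(e) list(F = -Inf))
      if (is.finite(cand$F) && cand$F > cur$F - 1e-12) {
        dF <- cand$F - cur$F
        theta <- cand_theta
        lambda <- cand_lambda
        cur <- cand
        improved <- TRUE
        break
      }
      nu <- max(nu, 1e-4) * 8
    }
    if (isTRUE(settings$verbose)) {
      message(sprintf("  iter %3d  F = %.3f  dF = %.4f  nu = %.2g  lambda = %.3g",
                      iter, cur$F, if (improved) dF else NA_real_, nu, lambda))
    }
    if (!improved) {
      converged <- TRUE  # no ascent direction left at heavy damping
      break
    }
    # small |dF| only signals convergence when the step was (near-)undamped
    streak <- if (abs(dF) < settings$tol && nu <= 1e-3) streak + 1L else 0L
    nu <- nu / 16  # relax damping quickly after success
    if (streak >= settings$tol_streak) {
      converged <- TRUE
      break
    }
  }

  structure(list(
    posterior_mean = setNames(theta, ptab$name),
    posterior_cov = structure(cur$Sigma, dimnames = list(ptab$name, ptab$name)),
    free_energy = cur$F, accuracy = cur$accuracy, complexity = cur$complexity,
    lambda = lambda, n_iterations = iter, converged = converged,
    model_id = spec$model_id, family_id = spec$family_id,
    param_table = ptab), class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("DCM inversion: F = %.2f nats, %d parameters, %d iterations (%s)\n",
              x$free_energy, length(x$posterior_mean), x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
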