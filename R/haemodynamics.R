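#' Balloon-windkessel haemodynamic parameters
#'
#' Parameters of the observation stage that maps neural activity to BOLD:
#' a vasodilatory signal s with decay `kappa` and autoregulation `gamma`
#' drives inflow f, which inflates venous volume v (stiffness exponent
#' `alpha`, transit time `tau`) and dilutes deoxyhaemoglobin q (resting
#' extraction `E0`). Defaults are the widely used constant set; they are
#' held fixed during inversion by default.
#'
#' @param kappa signal decay rate (1/s).
#' @param gamma autoregulation rate (1/s).
#' @param tau mean transit time (s).
#' @param alpha vessel stiffness exponent, in (0,1).
#' @param E0 resting oxygen extraction fraction, in (0,1).
#' @param V0 resting venous volume fraction.
#' @param epsilon neural efficacy scale (dimensionless).
#' @param k1,k2,k3 BOLD observation constants; defaults `7*E0`, `2`,
#'   `2*E0 - 0.2`.
#' @return A `haemo_params` object (named list).
#' @export
haemo_params <- function(kappa = 0.64, gamma = 0.32, tau = 2.0, alpha = 0.32,
                         E0 = 0.4, V0 = 0.04, epsilon = 1,
                         k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2) {
  vals <- c(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
            E0 = E0, V0 = V0, epsilon = epsilon)
  if (any(vals <= 0)) stop("all haemodynamic parameters must be strictly positive")
  if (alpha >= 1) stop("alpha must lie in (0, 1)")
  if (E0 >= 1) stop("E0 must lie in (0, 1)")
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 E0 = E0, V0 = V0, epsilon = epsilon,
                 k1 = k1, k2 = k2, k3 = k3),
            class = "haemo_params")
}

#' Haemodynamic state derivatives for one region
#'
#' The four coupled balloon-windkessel equations:
#' ds/dt = epsilon*z - kappa*s - gamma*(f - 1); df/dt = s;
#' dv/dt = (f - v^(1/alpha))/tau;
#' dq/dt = (f*E(f, E0)/E0 - v^(1/alpha)*q/v)/tau,
#' with oxygen extraction E(f, E0) = 1 - (1 - E0)^(1/f).
#' Rest (s = 0, f = v = q = 1, z = 0) is a fixed point.
#'
#' @param haemo_state numeric vector `c(s, f, v, q)`; `f` and `v` must be
#'   strictly positive.
#' @param z neural activity driving the region.
#' @param params a [haemo_params()] object.
#' @return named derivative vector `c(s, f, v, q)`.
#' @export
haemo_step <- function(haemo_state, z, params = haemo_params()) {
  s <- haemo_state[[1]]; f <- haemo_state[[2]]
  v <- haemo_state[[3]]; q <- haemo_state[[4]]
  if (f <= 0 || v <= 0) stop("inflow f and volume v must be strictly positive")
  E <- 1 - (1 - params$E0)^(1 / f)
  c(s = params$epsilon * z - params$kappa * s - params$gamma * (f - 1),
    f = s,
    v = (f - v^(1 / params$alpha)) / params$tau,
    q = (f * E / params$E0 - v^(1 / params$alpha) * q / v) / params$tau)
}

#' BOLD observation equation
#'
#' Maps a haemodynamic state trajectory to the (fractional) BOLD signal
#' y = V0 * (k1*(1 - q) + k2*(1 - q/v) + k3*(1 - v)). At rest (v = q = 1)
#' the signal is exactly zero.
#'
#' @param haemo_traj haemodynamic trajectory: either a 4 x T matrix (rows
#'   s, f, v, q) for one region or a 4n x T matrix of n stacked regions.
#' @param params a [haemo_params()] object.
#' @return a T-vector (one region) or T x n matrix of fractional BOLD.
#' @export
bold_observe <- function(haemo_traj, params = haemo_params()) {
  haemo_traj <- as.matrix(haemo_traj)
  if (nrow(haemo_traj) %% 4 != 0) {
    stop("haemodynamic trajectory must have 4 rows per region")
  }
  n <- nrow(haemo_traj) / 4
  out <- sapply(seq_len(n), function(i) {
    v <- haemo_traj[4 * (i - 1) + 3, ]
    q <- haemo_traj[4 * (i - 1) + 4, ]
    params$V0 * (params$k1 * (1 - q) + params$k2 * (1 - q / v) +
                   params$k3 * (1 - v))
  })
  if (n == 1) drop(out) else out
}

#' Simulate a sampled BOLD session
#'
#' Integrates the bilinear neural equation and the balloon observation
#' stage on a fine grid (RK4, bin width `dt`), reads the BOLD signal out at
#' every TR, scales it to percent signal change (`scale = 100`), and adds
#' independent Gaussian noise. Deterministic given `seed`.
#'
#' @param params a [dcm_params()] object.
#' @param haemo a [haemo_params()] object.
#' @param paradigm a [build_paradigm()] object.
#' @param noise_sd Gaussian noise standard deviation, in output units.
#' @param seed integer seed for the noise.
#' @param dt integration bin width (default TR/16).
#' @param inputs optionally a precomputed [build_inputs()] object.
#' @param baseline constant added to every sample (default 0, i.e. the
#'   series is pure signal change; use e.g. 100 to emulate grand-mean scaled
#'   scanner units).
#' @param scale multiplier applied to the fractional BOLD signal
#'   (default 100: percent units).
#' @return A `bold_timeseries` object: list with `y` (T x n matrix), `tr`,
#'   `times`, and `meta` (noise_sd, seed, baseline, scale).
#' @export
simulate_bold <- function(params, haemo = haemo_params(), paradigm,
                          noise_sd = 0, seed = 1, dt = paradigm$tr / 16,
                          inputs = NULL, baseline = 0, scale = 100) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(inputs)) inputs <- build_inputs(paradigm, dt = dt)
  samp <- sample_bins(paradigm, inputs$dt)
  fw <- cpp_dcm_forward(params$A, b_cube(params), params$C, inputs$u,
                        inputs$dt, unclass(haemo), samp - 1L,
                        rep(0, params$n), scale, FALSE)
  y <- fw$y + baseline
  if (noise_sd > 0) {
    y <- y + with_seed(seed, matrix(rnorm(length(y), 0, noise_sd), nrow(y)))
  }
  colnames(y) <- rownames(params$A)
  structure(list(y = y, tr = paradigm$tr,
                 times = (seq_len(nrow(y)) - 1) * paradigm$tr,
                 meta = list(noise_sd = noise_sd, seed = seed,
                             baseline = baseline, scale = scale)),
            class = "bold_timeseries")
}

# 1-based fine-grid bin indices of the volume acquisition times
sample_bins <- function(paradigm, dt) {
  bins <- round((seq_len(paradigm$n_volumes) - 1) * paradigm$tr / dt) + 1L
  n_bins <- ceiling(paradigm$n_volumes * paradigm$tr / dt - 1e-9)
  pmin(as.integer(bins), n_bins)
}

#' First eigenvariate of a set of voxel time series
#'
#' The standard ROI summary: the leading left singular vector of the T x k
#' voxel matrix scaled by its singular value, with the sign chosen so the
#' summary correlates positively with the mean voxel time course.
#'
#' @param voxel_ts T x k numeric matrix (T time points, k voxels), T > 1.
#' @return numeric T-vector.
#' @export
first_eigenvariate <- function(voxel_ts) {
  voxel_ts <- as.matrix(voxel_ts)
  if (nrow(voxel_ts) < 2) stop("need more than one time point")
  if (all(voxel_ts == 0)) stop("all-zero voxel matrix has no eigenvariate")
  sv <- svd(voxel_ts, nu = 1, nv = 0)
  ev <- sv$u[, 1] * sv$d[1]
  if (sum(ev * rowMeans(voxel_ts)) < 0) ev <- -ev
  ev
}

#' Emulate standard BOLD preprocessing of a time series
#'
#' Scales the session to a target grand mean, removes slow drifts with a
#' discrete-cosine high-pass filter at the given cutoff period, and
#' reinstates each region's mean level.
#'
#' @param ts a [simulate_bold()] object (or list with `y`, `tr`).
#' @param cutoff high-pass cutoff period in seconds (default 128 s, i.e.
#'   1/128 Hz); must exceed twice the TR.
#' @param target_mean grand-mean target (default 100).
#' @return a `bold_timeseries` with filtered `y`.
#' @export
preprocess_ts <- function(ts, cutoff = 128, target_mean = 100) {
  if (cutoff <= 2 * ts$tr) stop("cutoff must exceed twice the TR")
  y <- as.matrix(ts$y)
  gm <- mean(y)
  if (abs(gm) < .Machine$double.eps * 100) {
    stop("grand mean is zero; cannot scale")
  }
  y <- y * (target_mean / gm)
  T_ <- nrow(y)
  # DCT drift basis: orders with period 2*T*TR/k longer than the cutoff
  K <- floor(2 * T_ * ts$tr / cutoff)
  if (K >= 1) {
    tgrid <- seq_len(T_) - 0.5
    X <- sapply(seq_len(K), function(k) cos(pi * k * tgrid / T_))
    X <- qr.Q(qr(X))
    mu <- colMeans(y)
    yc <- sweep(y, 2, mu)
    y <- yc - X %*% crossprod(X, yc)
    y <- sweep(y, 2, mu, `+`)
  }
  out <- ts
  out$y <- y
  out$meta$preprocessed <- list(cutoff = cutoff, target_mean = target_mean)
  out
}

#' Write or read a region time-series table
#'
#' Tab-delimited text with a `time` first column and one column per region.
#'
#' @param ts a `bold_timeseries` (or `neural_trajectory`) object.
#' @param path file path.
#' @rdname timeseries_io
#' @export
write_timeseries <- function(ts, path) {
  if (inherits(ts, "neural_trajectory")) {
    tab <- data.frame(time = ts$times, t(ts$x), check.names = FALSE)
  } else {
    tab <- data.frame(time = ts$times, ts$y, check.names = FALSE)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param tr sampling interval of the stored table, seconds.
#' @rdname timeseries_io
#' @export
read_timeseries <- function(path, tr = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  y <- as.matrix(tab[, -1, drop = FALSE])
  if (is.null(tr)) tr <- if (nrow(tab) > 1) diff(tab$time[1:2]) else 1
  structure(list(y = y, tr = tr, times = tab$time, meta = list(path = path)),
            class = "bold_timeseries")
}
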