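#' Motor-network region set
#'
#' Defines the ordered set of cortical regions in the network. The default is
#' the eight-region hand-grip motor network: primary motor cortex (M1),
#' supplementary motor area (SMA), dorsal premotor cortex (PMd) and ventral
#' premotor cortex (PMv) in each hemisphere. Labels must end in `_L` or `_R`
#' so the hemisphere of every region is parseable; M1 acts as the hub of the
#' modulatory model families and all other areas are "secondary" motor areas.
#'
#' @param labels character vector of unique region labels with `_L`/`_R`
#'   hemisphere suffixes.
#' @param coordinates optional numeric matrix (regions x 3) of MNI
#'   coordinates in mm; metadata only, never used in computation.
#' @return An object of class `region_set`: a list with `labels`,
#'   `hemisphere` (`"L"`/`"R"` per region), `area` (label without suffix),
#'   `n`, and `coordinates`.
#' @examples
#' r <- region_set()
#' r$n                      # 8
#' reduced_region_set()$n   # 4
#' @export
region_set <- function(labels = c("M1_L", "M1_R", "SMA_L", "SMA_R",
                                  "PMd_L", "PMd_R", "PMv_L", "PMv_R"),
                       coordinates = NULL) {
  if (anyDuplicated(labels)) stop("region labels must be unique")
  hemi <- sub("^.*_([LR])$", "\\1", labels)
  ok <- grepl("_[LR]$", labels)
  if (!all(ok)) {
    stop("region labels must carry a parseable hemisphere suffix (_L or _R): ",
         paste(labels[!ok], collapse = ", "))
  }
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    stopifnot(nrow(coordinates) == length(labels), ncol(coordinates) == 3)
    rownames(coordinates) <- labels
  }
  structure(list(labels = labels, hemisphere = hemi,
                 area = sub("_[LR]$", "", labels),
                 n = length(labels), coordinates = coordinates),
            class = "region_set")
}

#' @rdname region_set
#' @details `reduced_region_set()` returns the four-region network
#'   (bilateral M1 and SMA) used to keep inversion-heavy simulation studies
#'   at desk scale; the model-family construction applies to it unchanged
#'   with SMA as the single secondary area per hemisphere.
#' @export
reduced_region_set <- function() {
  region_set(c("M1_L", "M1_R", "SMA_L", "SMA_R"))
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Event-related hand-grip paradigm
#'
#' Builds a randomised, counterbalanced event sequence at a fixed
#' stimulus-onset asynchrony (SOA). The default reproduces the study design:
#' 100 visually cued grips (20 at each of 15, 25, 35, 45 and 55% of maximum
#' voluntary contraction) interleaved with 60 null events for jitter,
#' SOA 3.77 s, sampled over 196 volumes at TR 3.12 s.
#'
#' @param levels grip-force levels in % MVC.
#' @param reps_per_level grips per force level.
#' @param n_null number of null (rest) events interleaved for jitter.
#' @param soa stimulus-onset asynchrony in seconds; must be positive.
#' @param tr volume repetition time in seconds.
#' @param n_volumes number of retained volumes per session.
#' @param seed integer seed for the event-order randomisation.
#' @return A `paradigm` object: list with `events` (data.frame of `onset`
#'   seconds, `kind` grip/null, `force` % MVC or NA), `soa`, `tr`,
#'   `n_volumes`.
#' @examples
#' p <- build_paradigm(seed = 1)
#' table(p$events$kind)  # 100 grips, 60 nulls
#' @export
build_paradigm <- function(levels = c(15, 25, 35, 45, 55),
                           reps_per_level = 20, n_null = 60, soa = 3.77,
                           tr = 3.12, n_volumes = 196, seed = 1) {
  if (length(levels) < 1) stop("invalid configuration: need at least one force level")
  if (reps_per_level < 1) stop("invalid configuration: reps_per_level must be >= 1")
  if (soa <= 0) stop("invalid configuration: SOA must be positive")
  if (n_null < 0) stop("invalid configuration: n_null must be >= 0")
  forces <- rep(levels, each = reps_per_level)
  kind <- c(rep("grip", length(forces)), rep("null", n_null))
  force <- c(forces, rep(NA_real_, n_null))
  ord <- with_seed(seed, sample.int(length(kind)))
  events <- data.frame(onset = (seq_along(kind) - 1) * soa,
                       kind = kind[ord], force = force[ord])
  structure(list(events = events, soa = soa, tr = tr, n_volumes = n_volumes),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("Paradigm: %d grip / %d null events, SOA %.2f s, TR %.2f s, %d volumes\n",
              sum(x$events$kind == "grip"), sum(x$events$kind == "null"),
              x$soa, x$tr, x$n_volumes))
  invisible(x)
}

#' Experimental input functions on the integration grid
#'
#' Converts a paradigm into the two DCM input channels on a fine time grid:
#' a driving channel with a unit-area impulse (one bin of height `1/dt`) at
#' every grip onset, and a modulatory channel carrying the grip-force
#' deviation at the same bins. Forces are expressed as MVC fractions and,
#' by default, mean-centred across grip events so the modulatory coupling
#' matrices express deviation from the average-force condition; the
#' modulatory channel is impulse-coded the same way (area equals the centred
#' force value). Null events produce nothing.
#'
#' @param paradigm a [build_paradigm()] object.
#' @param dt grid bin width in seconds; must be positive and at most TR/8.
#'   Default TR/16.
#' @param center mean-centre the force covariate (default TRUE); with
#'   `FALSE` the raw MVC fraction is used.
#' @return An `input_functions` object: list with `u` (2 x n_bins matrix,
#'   rows driving/modulatory), `dt`, `m = 2`, `channels`, and `grip_bins`.
#' @examples
#' u <- build_inputs(build_paradigm(seed = 1))
#' sum(u$u[1, ] > 0)  # 100 driving impulses
#' @export
build_inputs <- function(paradigm, dt = paradigm$tr / 16, center = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  if (dt > paradigm$tr / 8 + 1e-12) stop("dt must be at most TR/8")
  duration <- paradigm$n_volumes * paradigm$tr
  n_bins <- ceiling(duration / dt - 1e-9)
  u <- matrix(0, 2, n_bins,
              dimnames = list(c("driving", "modulatory"), NULL))
  grips <- paradigm$events[paradigm$events$kind == "grip", , drop = FALSE]
  grip_bins <- integer(0)
  if (nrow(grips) > 0) {
    grip_bins <- pmin(floor(grips$onset / dt + 1e-9) + 1L, n_bins)
    fr <- grips$force / 100
    if (center) fr <- fr - mean(fr)
    for (k in seq_len(nrow(grips))) {
      u[1, grip_bins[k]] <- u[1, grip_bins[k]] + 1 / dt
      u[2, grip_bins[k]] <- u[2, grip_bins[k]] + fr[k] / dt
    }
  }
  structure(list(u = u, dt = dt, m = 2L,
                 channels = c("driving", "modulatory"),
                 grip_bins = grip_bins),
            class = "input_functions")
}

#' Bilinear coupling parameters
#'
#' Container for the coupling matrices of the bilinear neural state
#' equation dx/dt = (A + sum_j u_j B_j) x + C u. `A` holds intrinsic
#' coupling rates (1/s; entry `A[i, j]` is the influence of region j on
#' region i), each `B[[j]]` the input-dependent change in coupling for input
#' channel j, and `C` the driving-input weights. Self-connections (diagonal
#' of A) must be strictly negative for stability; inversion parameterises
#' them as -0.5 * exp(theta) so any real theta is admissible.
#'
#' @param A n x n intrinsic coupling matrix (1/s), negative diagonal.
#' @param B list of m n x n modulatory matrices (1/s), or NULL for all-zero.
#' @param C n x m driving weight matrix (1/s), or NULL for all-zero.
#' @param m number of input channels (used when B or C is NULL).
#' @return A `dcm_params` object (list with `A`, `B`, `C`, `n`, `m`).
#' @export
dcm_params <- function(A, B = NULL, C = NULL, m = 2L) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (any(diag(A) >= 0)) stop("diagonal of A must be strictly negative")
  if (is.null(B)) B <- replicate(m, matrix(0, n, n), simplify = FALSE)
  if (!is.list(B)) B <- list(B)
  m <- length(B)
  for (j in seq_len(m)) {
    B[[j]] <- as.matrix(B[[j]])
    if (!all(dim(B[[j]]) == c(n, n))) {
      stop(sprintf("B[[%d]] has dimensions %dx%d; expected %dx%d",
                   j, nrow(B[[j]]), ncol(B[[j]]), n, n))
    }
  }
  if (is.null(C)) C <- matrix(0, n, m)
  C <- as.matrix(C)
  if (nrow(C) != n || ncol(C) != m) {
    stop(sprintf("C has dimensions %dx%d; expected %dx%d", nrow(C), ncol(C), n, m))
  }
  structure(list(A = A, B = B, C = C, n = n, m = m), class = "dcm_params")
}

b_cube <- function(params) {
  arr <- array(0, c(params$n, params$n, params$m))
  for (j in seq_len(params$m)) arr[, , j] <- params$B[[j]]
  arr
}

#' Bilinear neural state derivative
#'
#' Evaluates dx/dt = (A + sum_j u_j B_j) x + C u at one time bin.
#'
#' @param x neural state vector (length n).
#' @param params a [dcm_params()] object.
#' @param u input values at this bin (length m).
#' @return the state-derivative vector.
#' @examples
#' p <- dcm_params(A = diag(-0.5, 2), m = 1)
#' neural_derivative(c(1, 1), p, 0)  # equals A %*% x
#' @export
neural_derivative <- function(x, params, u) {
  if (length(x) != params$n) {
    stop(sprintf("state x has length %d but A is %dx%d",
                 length(x), params$n, params$n))
  }
  if (length(u) != params$m) {
    stop(sprintf("input u has length %d but there are %d B/C input channels",
                 length(u), params$m))
  }
  M <- params$A
  for (j in seq_len(params$m)) {
    if (u[j] != 0) M <- M + u[j] * params$B[[j]]
  }
  drop(M %*% x + params$C %*% u)
}

#' Integrate the bilinear neural state equation
#'
#' Fixed-step classical 4th-order Runge-Kutta on the input grid; inputs are
#' held constant over each bin. Deterministic.
#'
#' @param params a [dcm_params()] object.
#' @param inputs a [build_inputs()] object (or any list with `u`, `dt`).
#' @param x0 initial state (default zero).
#' @return A `neural_trajectory` object: list with `x` (n x n_bins matrix of
#'   states at bin start times), `dt`, `times`.
#' @export
integrate_neural <- function(params, inputs, x0 = rep(0, params$n)) {
  if (length(x0) != params$n) stop("x0 length does not match the network size")
  X <- cpp_integrate_neural(params$A, b_cube(params), params$C, inputs$u,
                            inputs$dt, as.numeric(x0))
  rownames(X) <- rownames(params$A)
  structure(list(x = X, dt = inputs$dt,
                 times = (seq_len(ncol(X)) - 1) * inputs$dt),
            class = "neural_trajectory")
}
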