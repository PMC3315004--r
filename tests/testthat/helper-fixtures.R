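# Shared fixtures: tiny networks and short paradigms that keep ODE
# integration cheap while exercising every code path.

# short session: 10 grips over two force levels, ~75 s
short_paradigm <- function(seed = 1, n_volumes = 24) {
  build_paradigm(levels = c(30, 50), reps_per_level = 5, n_null = 2,
                 soa = 3.77, tr = 3.12, n_volumes = n_volumes, seed = seed)
}

# stable 2-region parameters with one directed connection; m = 1 gives a
# single driving channel, m = 2 the standard driving + modulatory pair
two_region_params <- function(a21 = 0.2, b21 = 0.3, c1 = 1, m = 1) {
  A <- matrix(c(-0.5, a21, 0, -0.5), 2, 2,
              dimnames = list(c("R1", "R2"), c("R1", "R2")))
  B <- matrix(0, 2, 2, dimnames = dimnames(A))
  B[2, 1] <- b21
  if (m == 1) {
    dcm_params(A, list(B), matrix(c(c1, 0), 2, 1))
  } else {
    C <- matrix(0, 2, m); C[1, 1] <- c1
    dcm_params(A, c(list(matrix(0, 2, 2)), rep(list(B), m - 1)), C)
  }
}

# three-region chain used for recovery studies; couplings on the scale of
# the group-average table
three_region_truth <- function() {
  labs <- c("M1_L", "M1_R", "SMA_L")
  A <- matrix(c(-0.5, 0.10, 0.16,
                0.12, -0.5, 0.05,
                0.14, -0.08, -0.5), 3, 3, byrow = FALSE,
              dimnames = list(labs, labs))
  # column-major above: col 1 = sources from M1_L
  B <- matrix(0, 3, 3, dimnames = dimnames(A))
  B["M1_R", "M1_L"] <- -0.6
  C <- matrix(0, 3, 2, dimnames = list(labs, c("driving", "modulatory")))
  C[c("M1_L", "SMA_L"), 1] <- c(1.2, 0.3)
  dcm_params(A, list(matrix(0, 3, 3), B), C)
}

# model spec over an arbitrary region set with everything allowed in A,
# the given modulatory mask and driving input into left-hemisphere regions
free_model_spec <- function(labels, b_mask = NULL, model_id = 1L,
                            family_id = 1L) {
  n <- length(labels)
  a <- matrix(1L, n, n, dimnames = list(labels, labels))
  if (is.null(b_mask)) b_mask <- matrix(0L, n, n, dimnames = dimnames(a))
  cm <- matrix(0L, n, 2,
               dimnames = list(labels, c("driving", "modulatory")))
  cm[grepl("_L$", labels), 1] <- 1L
  structure(list(model_id = model_id, family_id = family_id, a_mask = a,
                 b_masks = list(driving = matrix(0L, n, n,
                                                 dimnames = dimnames(a)),
                                modulatory = b_mask),
                 c_mask = cm, modulated = character(0), self_variant = "all"),
            class = "model_spec")
}

# fast inversion settings for unit tests
quick_settings <- function() inversion_settings(max_iter = 48)
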