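# Independent brute-force oracles the implementation is checked against.

# O(n^2) pairwise non-dominated filter using only the dominance predicate
oracle_non_dominated <- function(points) {
  n <- nrow(points)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(points[j, ], points[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# largest canonical correlation via the textbook eigenproblem
# inv(Sxx) Sxy inv(Syy) Syx, built directly from centered cross-covariances
oracle_max_cancor <- function(x, y) {
  x <- scale(x, scale = FALSE)
  y <- scale(y, scale = FALSE)
  sxx <- crossprod(x); syy <- crossprod(y); sxy <- crossprod(x, y)
  m <- solve(sxx, sxy) %*% solve(syy, t(sxy))
  sqrt(max(0, max(Re(eigen(m)$values))))
}

# tiny epoch set with white-noise background for fast unit tests
tiny_epochs <- function(n_trials = 8L, n_channels = 3L, n_samples = 64L,
                        fs = 64, labels = rep(c("a", "b"), length.out = n_trials),
                        seed = 1L) {
  set.seed(seed)
  data <- array(rnorm(n_trials * n_channels * n_samples),
                dim = c(n_trials, n_channels, n_samples))
  epoch_set(data, labels, fs, paste0("ch", seq_len(n_channels)))
}

# small, fast synthetic scene shared by integration-style tests
fast_synth_config <- function(...) {
  defaults <- list(trial_sec = 1, mi_trials_per_class = 10L,
                   ssvep_trials_per_class = 6L)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# compact EA configuration for pipeline tests
fast_ea_config <- function(...) {
  args <- list(...)
  defaults <- list(pop_size = 20L, budget = 400L, max_generations = 5L,
                   archive_cap = 30L)
  do.call(ea_config, utils::modifyList(defaults, args))
}

as_mask <- function(names, montage = default_montage()) {
  as.integer(montage %in% names)
}
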