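# Shared fixtures: trials are simulated once per test run and cached, since
# several test files interrogate the same records.

.trial_cache <- new.env(parent = emptyenv())

cached_trial <- function(mode, sigh = FALSE, cycles = 60L, seed = 1L,
                         config = default_config()) {
  key <- paste(mode, sigh, cycles, seed, config_key(config), sep = "|")
  if (is.null(.trial_cache[[key]]))
    .trial_cache[[key]] <- simulate_trial(config, mode = mode, sigh = sigh,
                                          pacing_cycles = cycles, seed = seed)
  .trial_cache[[key]]
}

config_key <- function(config) {
  paste(unlist(config), collapse = ",")
}

cached_cohort <- function(seed = 1L) {
  key <- paste0("cohort", seed)
  if (is.null(.trial_cache[[key]]))
    .trial_cache[[key]] <- run_cohort(default_config(), n_subjects = 6L,
                                      pacing_cycles = 550L, seed = seed)
  .trial_cache[[key]]
}

# brute-force O(n^2) window scan used as the oracle for the run detectors
brute_force_onset <- function(x, threshold, run_length, inclusive) {
  n <- length(x)
  ok <- if (inclusive) x <= threshold else x < threshold
  ok[is.na(ok)] <- FALSE
  for (i in seq_len(n - run_length + 1L)) {
    if (all(ok[i:(i + run_length - 1L)])) return(i)
  }
  NA_integer_
}

# exact Wilcoxon oracle: enumerate all 2^n sign assignments of the ranks
enumerate_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  mean(W_all >= W_obs - 1e-12)
}
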