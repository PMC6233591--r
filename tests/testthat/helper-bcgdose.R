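# Shared test utilities: an independent brute-force oracle for the cohort
# distribution and a generator of random valid parameter sets.

# Exact state distribution after t steps of a single-patient Markov chain,
# by enumerating all 5^t state paths and summing path probabilities.
# Deliberately independent of the engine's matrix-power iteration.
enumerate_distribution <- function(M, t, start = 1L) {
  stopifnot(t >= 1, t <= 6)
  paths <- as.matrix(expand.grid(rep(list(1:5), t)))
  out <- numeric(5)
  for (i in seq_len(nrow(paths))) {
    pth <- c(start, paths[i, ])
    pr <- prod(M[cbind(pth[-length(pth)], pth[-1])])
    out[pth[length(pth)]] <- out[pth[length(pth)]] + pr
  }
  out
}

# Random parameter set satisfying all invariants with slack.
random_valid_params <- function() {
  bcg_parameters(
    age_mortality = runif(1, 0.01, 0.3),
    ld_rec_no_worse = runif(1, 0, 0.2),
    ld_rec_worse = runif(1, 0, 0.2),
    fd_rec_no_worse = runif(1, 0, 0.2),
    fd_rec_worse = runif(1, 0, 0.2),
    rc_mortality = runif(1, 0, 0.3),
    met_after_rc = runif(1, 0, 0.3),
    met_death = runif(1, 0.1, 0.9)
  )
}
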