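# Test fixtures are generated in code: no data files.

# random right-censored cohort with ties and (optionally) fractional weights
random_cohort <- function(n, seed, p_event = 0.7, fractional_weights = FALSE) {
  set.seed(seed)
  time <- round(stats::rweibull(n, shape = stats::runif(1, 0.6, 1.6),
                                scale = stats::runif(1, 1, 6)), 2) + 0.01
  event <- stats::rbinom(n, 1, p_event)
  if (sum(event) == 0) event[1] <- 1
  w <- if (fractional_weights) stats::runif(n, 0.5, 3) else 1
  cohort(time = time, event = event, weight = w)
}

# brute-force Nelson-Aalen oracle: walks the distinct event times one at a
# time with scalar sums, independent of the vectorized implementation
na_oracle <- function(time, event, weight = rep(1, length(time))) {
  et <- sort(unique(time[event == 1]))
  H <- V <- numeric(length(et))
  h <- v <- 0
  for (i in seq_along(et)) {
    d <- 0
    Y <- 0
    for (j in seq_along(time)) {
      if (time[j] == et[i] && event[j] == 1) d <- d + weight[j]
      if (time[j] >= et[i]) Y <- Y + weight[j]
    }
    h <- h + d / Y
    v <- v + d / Y^2
    H[i] <- h
    V[i] <- v
  }
  list(times = et, H = H, V = V)
}

# quiet wrapper for fits whose convergence chatter is not under test
fit_quiet <- function(...) suppressWarnings(fit_parametric(...))
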