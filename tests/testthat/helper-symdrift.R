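# Shared test fixtures and independent oracles.

basic_params <- function(N = 1e4, mu = 0.001, fitness = 1.1, sh = 0, cv = 0) {
  model_params(
    N = N,
    transmission = transmission_profile(mu),
    fitness = fitness_spec(fitness, cv = cv),
    sh = sh
  )
}

lt_params <- function(N = 1e4, mu = 0.001, fitness = 1.1, sh = 0) {
  model_params(
    N = N,
    transmission = low_transmitter_profile(mu),
    fitness = fitness_spec(fitness),
    sh = sh
  )
}

# Independent fixed-point oracle: iterate the one-generation map until the
# update is below tol, starting from p_start.
iterate_to_fixed_point <- function(fitness, mu, sh, p_start = 0.5,
                                   tol = 1e-14, max_iter = 1e6L) {
  p <- p_start
  for (i in seq_len(max_iter)) {
    p_next <- project_frequency(p, fitness, mu, sh)
    if (abs(p_next - p) < tol) return(p_next)
    p <- p_next
  }
  p
}

# Two-sample chi-square on integer-valued draws, pooling sparse tail bins so
# every expected cell count is at least 5.
two_sample_chisq_p <- function(x, y) {
  values <- sort(unique(c(x, y)))
  tab <- rbind(
    tabulate(match(x, values), nbins = length(values)),
    tabulate(match(y, values), nbins = length(values))
  )
  # pool adjacent bins until each column total gives expected counts >= 5
  min_total <- 10L
  pooled <- list()
  acc <- c(0L, 0L)
  for (j in seq_len(ncol(tab))) {
    acc <- acc + tab[, j]
    if (sum(acc) >= min_total) {
      pooled[[length(pooled) + 1L]] <- acc
      acc <- c(0L, 0L)
    }
  }
  if (sum(acc) > 0 && length(pooled)) {
    pooled[[length(pooled)]] <- pooled[[length(pooled)]] + acc
  }
  m <- do.call(cbind, pooled)
  suppressWarnings(stats::chisq.test(m)$p.value)
}
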