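#' Draw per-generation relative fitness values
#'
#' In fixed mode every draw equals the specified value. In log-normal mode
#' draws are `exp(X)` with `X ~ Normal(log(m), log(cv^2 + 1))`, so their
#' median converges to `m` and their coefficient of variation to `cv`.
#' Draws consume the R random number stream only in log-normal mode.
#'
#' @param spec A [fitness_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' summary(draw_fitness(fitness_spec(1.05, cv = 0.1), 1000))
#' @export
draw_fitness <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "fitness_spec"), n >= 0)
  if (spec$mode == "fixed" || spec$sigma == 0) {
    return(rep(spec$median, n))
  }
  rlnorm(n, meanlog = spec$mu_x, sdlog = spec$sigma)
}

# Core one-generation offspring sampler: n independent draws of the
# next-generation frequency given (p, I). All randomness lives in offspring
# infection status; CI mortality enters as deterministic thinning through
# the denominator. Non-integer binomial trial counts are rounded half to
# even. Returns a numeric vector of length n.
sample_offspring_frequency <- function(p, I, params, f_t, n = 1L) {
  N <- params$N
  sh <- params$sh
  r <- params$transmission$groups$fraction
  mu <- params$transmission$groups$mu
  M <- length(r)
  if (I == 0 || p == 0) return(numeric(n))
  if (sh == 0) {
    sizes <- round(f_t * r * I)
    draws <- rbinom(M * n, size = sizes, prob = 1 - mu)
    S <- if (M == 1L) draws else colSums(matrix(draws, nrow = M))
    pnew <- (S / N) / (p * (f_t - 1) + 1)
  } else {
    y_sizes <- round(f_t * p * r * I)
    z_sizes <- round(f_t * (1 - p) * r * I)
    yd <- rbinom(M * n, size = y_sizes, prob = 1 - mu)
    zd <- rbinom(M * n, size = z_sizes, prob = 1 - mu)
    x1 <- (if (M == 1L) yd else colSums(matrix(yd, nrow = M))) / N
    x2 <- (if (M == 1L) zd else colSums(matrix(zd, nrow = M))) / N
    denom <- sh * (1 - f_t) * p^2 + (f_t - sh - 1) * p + sh * x1 + 1
    if (any(denom <= 0)) {
      abort("stochastic step: non-positive denominator; state outside the valid domain.")
    }
    pnew <- (x1 + x2) / denom
  }
  # Rounded trial counts can overshoot the exact offspring total by at most
  # 1/2 per subgroup; anything beyond that indicates a bookkeeping error.
  if (any(pnew < 0) || any(pnew > 1 + M / N)) {
    abort("stochastic step: frequency outside [0, 1]; bookkeeping violated.")
  }
  pmin(pnew, 1)
}

advance_state <- function(state, pnew, N) {
  I <- round(N * pnew)
  if (I == 0) pnew <- 0  # absorbing: p = 0 iff I = 0
  structure(
    list(t = state$t + 1L, p = pnew, I = I),
    class = "population_state"
  )
}

#' One stochastic generation without cytoplasmic incompatibility
#'
#' For each transmission subgroup `i`, draws the infected offspring count
#' `X_i ~ Binomial(round(F_t * r_i * I), 1 - mu_i)` and forms the
#' next-generation frequency `p' = (sum(X_i) / N) / (p (F_t - 1) + 1)`, then
#' `I' = round(N p')`. An empty infected class short-circuits to the
#' absorbed state.
#'
#' @param state A [population_state()].
#' @param params A [model_params()] with `sh = 0`.
#' @param f_t Relative fitness acting this generation (one value shared by
#'   all females).
#' @return The next [population_state()].
#' @export
step_no_ci <- function(state, params, f_t) {
  stopifnot(inherits(params, "model_params"))
  if (params$sh != 0) abort("step_no_ci requires sh = 0; use step_ci.")
  pnew <- sample_offspring_frequency(state$p, state$I, params, f_t, n = 1L)
  advance_state(state, pnew, params$N)
}

#' One stochastic generation with cytoplasmic incompatibility
#'
#' Draws, per subgroup, infected offspring from infected-father matings
#' `Y_i ~ Binomial(round(F_t p r_i I), 1 - mu_i)` and from uninfected-father
#' matings `Z_i ~ Binomial(round(F_t (1 - p) r_i I), 1 - mu_i)`. With
#' normalised sums `X1 = sum(Y_i)/N`, `X2 = sum(Z_i)/N`, the next frequency
#' is
#' \deqn{p' = \frac{\tilde X_1 + \tilde X_2}{s_h (1 - F_t) p^2 +
#'   (F_t - s_h - 1) p + s_h \tilde X_1 + 1},}
#' where CI mortality of uninfected ova fathered by infected males enters as
#' the deterministic thinning implicit in the denominator. With `sh = 0` the
#' update delegates to [step_no_ci()] (same random stream, same trial
#' rounding).
#'
#' @inheritParams step_no_ci
#' @param params A [model_params()].
#' @return The next [population_state()].
#' @export
step_ci <- function(state, params, f_t) {
  stopifnot(inherits(params, "model_params"))
  if (params$sh == 0) return(step_no_ci(state, params, f_t))
  pnew <- sample_offspring_frequency(state$p, state$I, params, f_t, n = 1L)
  advance_state(state, pnew, params$N)
}

#' Conditional mean and variance of the next frequency (no CI)
#'
#' Closed-form first two moments of the one-step transition given the
#' current frequency, for `sh = 0`:
#' \deqn{E[p_{t+1} \mid p_t] = \frac{F (1 - \bar\mu) p}{p (F - 1) + 1},
#' \quad
#' Var[p_{t+1} \mid p_t] = \frac{p \sum_i F r_i \mu_i (1 - \mu_i)}
#'   {N \, (p (F - 1) + 1)^2},}
#' the variance following from additivity over the independent per-subgroup
#' binomials; a single group reduces it to
#' `F mu (1 - mu) p / (N (p (F - 1) + 1)^2)`. These are exact when the
#' binomial trial counts `F r_i I` are integers and accurate to `O(1/N)`
#' otherwise. Moments for the CI recursion have no closed form here and are
#' validated empirically (see [moment_check()]).
#'
#' @param p Current frequency.
#' @param params A [model_params()] with `sh = 0`.
#' @param f_t Fitness value acting this generation.
#' @return A one-row tibble with columns `mean` and `variance`.
#' @examples
#' conditional_moments(0.5, model_params(100, 0.1, 1), f_t = 1)
#' @export
conditional_moments <- function(p, params, f_t) {
  stopifnot(inherits(params, "model_params"), p >= 0, p <= 1)
  if (params$sh != 0) {
    abort("conditional_moments: closed forms require sh = 0.")
  }
  r <- params$transmission$groups$fraction
  mu <- params$transmission$groups$mu
  mu_bar <- params$transmission$mu_bar
  denom <- p * (f_t - 1) + 1
  tibble(
    mean = f_t * (1 - mu_bar) * p / denom,
    variance = p * sum(f_t * r * mu * (1 - mu)) / (params$N * denom^2)
  )
}

#' Simulate one stochastic trajectory
#'
#' Runs the finite-population recursion for `protocol$generations`
#' generations from `protocol$p0`. Each generation draws one fitness value
#' (shared by all females) from the fitness spec, then applies the CI-aware
#' stochastic step. Loss (`p = 0`) is absorbing. The same seed reproduces
#' the trajectory bit-exactly.
#'
#' @param params A [model_params()].
#' @param protocol A [sim_protocol()]; only `p0` and `generations` are used
#'   here.
#' @param seed Integer seed for this trajectory; defaults to
#'   `protocol$base_seed`.
#' @param adult_resampling If `TRUE`, adds an adult-sampling stage
#'   `I' ~ Binomial(N, p')`, `p' = I'/N`, an alternative reading in which
#'   the next adult generation is itself a binomial sample of the offspring
#'   frequency. Default `FALSE`: all randomness lives in offspring
#'   infection status and `I' = round(N p')`, matching the printed
#'   recursions and their conditional moments.
#' @return A tibble of class `symdrift_trajectory` with columns
#'   `generation` (0..T), `p`, `I`, and `f_t` (fitness that produced the
#'   generation; `NA` at generation 0), and attributes `params`, `protocol`,
#'   `seed`, `adult_resampling`, and `absorbed_at` (first generation with
#'   `p = 0`, or `NA`).
#' @examples
#' pars <- model_params(1e4, transmission = 0.001, fitness = 1.1)
#' traj <- simulate_trajectory(pars, sim_protocol(generations = 1000), seed = 1)
#' tail(traj)
#' @export
simulate_trajectory <- function(params, protocol = sim_protocol(),
                                seed = NULL, adult_resampling = FALSE) {
  stopifnot(inherits(params, "model_params"), inherits(protocol, "sim_protocol"))
  seed <- as.integer(seed %||% protocol$base_seed)
  set.seed(seed)
  N <- params$N
  sh <- params$sh
  r <- params$transmission$groups$fraction
  mu <- params$transmission$groups$mu
  M <- length(r)
  T_gen <- protocol$generations
  f <- draw_fitness(params$fitness, T_gen)

  p <- numeric(T_gen + 1)
  I <- numeric(T_gen + 1)
  p[1] <- protocol$p0
  I[1] <- round(N * protocol$p0)
  if (I[1] == 0) p[1] <- 0
  absorbed_at <- if (p[1] == 0) 0L else NA_integer_

  for (t in seq_len(T_gen)) {
    pt <- p[t]
    It <- I[t]
    if (It == 0) {
      # absorbed: remainder of the trajectory is zero
      break
    }
    ft <- f[t]
    if (sh == 0) {
      S <- sum(rbinom(M, size = round(ft * r * It), prob = 1 - mu))
      pn <- (S / N) / (pt * (ft - 1) + 1)
    } else {
      y <- sum(rbinom(M, size = round(ft * pt * r * It), prob = 1 - mu))
      z <- sum(rbinom(M, size = round(ft * (1 - pt) * r * It), prob = 1 - mu))
      x1 <- y / N
      denom <- sh * (1 - ft) * pt^2 + (ft - sh - 1) * pt + sh * x1 + 1
      if (denom <= 0) {
        abort("simulate_trajectory: non-positive denominator; bookkeeping violated.")
      }
      pn <- (x1 + z / N) / denom
    }
    if (pn < 0 || pn > 1 + M / N) {
      abort("simulate_trajectory: frequency outside [0, 1]; bookkeeping violated.")
    }
    pn <- min(pn, 1)
    if (adult_resampling) {
      In <- rbinom(1, N, pn)
      pn <- In / N
    } else {
      In <- round(N * pn)
    }
    if (In == 0) pn <- 0
    p[t + 1] <- pn
    I[t + 1] <- In
    if (pn == 0 && is.na(absorbed_at)) absorbed_at <- t
  }

  out <- tibble(
    generation = 0:T_gen,
    p = p,
    I = I,
    f_t = c(NA_real_, f)
  )
  structure(
    out,
    params = params,
    protocol = protocol,
    seed = seed,
    adult_resampling = adult_resampling,
    absorbed_at = absorbed_at,
    class = c("symdrift_trajectory", class(out))
  )
}

#' @method tidy symdrift_trajectory
#' @export
tidy.symdrift_trajectory <- function(x, ...) {
  as_tibble(x)
}
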