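#' Individual-based oracle step without cytoplasmic incompatibility
#'
#' Brute-force re-derivation of the one-generation transition used only to
#' validate the stochastic engine: instead of drawing per-subgroup binomial
#' offspring counts, every ovum is enumerated. Each subgroup of infected
#' females produces `round(F_t * r_i * I)` ova, each independently infected
#' with probability `1 - mu_i`; the next frequency uses the same census
#' ratio as the engine, `p' = (S / N) / (p (F_t - 1) + 1)`. In law this
#' per-ovum Bernoulli sum equals the engine's binomial draw. Never called by
#' production code paths.
#'
#' @param p Current frequency.
#' @param I Infected female count (`round(N * p)`).
#' @param params A [model_params()] with `sh = 0`.
#' @param f_t Fitness value acting this generation.
#' @return The next-generation frequency (numeric scalar).
#' @export
oracle_step_no_ci <- function(p, I, params, f_t) {
  stopifnot(inherits(params, "model_params"))
  if (params$sh != 0) abort("oracle_step_no_ci requires sh = 0.")
  if (I == 0 || p == 0) return(0)
  r <- params$transmission$groups$fraction
  mu <- params$transmission$groups$mu
  S <- 0
  for (i in seq_along(r)) {
    n_ova <- round(f_t * r[i] * I)
    if (n_ova > 0) S <- S + sum(runif(n_ova) < 1 - mu[i])
  }
  (S / params$N) / (p * (f_t - 1) + 1)
}

#' Individual-based oracle step with cytoplasmic incompatibility
#'
#' Per-ovum enumeration of the CI recursion. Infected females' ova are split
#' by father status (fraction `p` infected, `1 - p` uninfected); each ovum
#' is infected with probability `1 - mu_i` of its mother's subgroup. By
#' default CI mortality is the same deterministic thinning the engine's
#' denominator encodes, so the oracle validates the printed recursion. With
#' `ci_bernoulli = TRUE`, each uninfected ovum fathered by an infected male
#' instead survives an independent Bernoulli(`1 - sh`) trial and the
#' denominator uses realised counts — a sensitivity variant, not the model
#' under test.
#'
#' @inheritParams oracle_step_no_ci
#' @param params A [model_params()].
#' @param ci_bernoulli Use per-ovum Bernoulli CI survival (see Details).
#' @return The next-generation frequency (numeric scalar).
#' @export
oracle_step_ci <- function(p, I, params, f_t, ci_bernoulli = FALSE) {
  stopifnot(inherits(params, "model_params"))
  if (params$sh == 0) return(oracle_step_no_ci(p, I, params, f_t))
  if (I == 0 || p == 0) return(0)
  N <- params$N
  sh <- params$sh
  r <- params$transmission$groups$fraction
  mu <- params$transmission$groups$mu
  y <- 0  # infected offspring, infected father
  z <- 0  # infected offspring, uninfected father
  y_uninf <- 0  # uninfected ova with infected father (CI-exposed)
  for (i in seq_along(r)) {
    ny <- round(f_t * p * r[i] * I)
    nz <- round(f_t * (1 - p) * r[i] * I)
    if (ny > 0) {
      inf <- sum(runif(ny) < 1 - mu[i])
      y <- y + inf
      y_uninf <- y_uninf + (ny - inf)
    }
    if (nz > 0) z <- z + sum(runif(nz) < 1 - mu[i])
  }
  x1 <- y / N
  x2 <- z / N
  if (!ci_bernoulli) {
    denom <- sh * (1 - f_t) * p^2 + (f_t - sh - 1) * p + sh * x1 + 1
    return((x1 + x2) / denom)
  }
  # Bernoulli CI survival: realised survivors among all CI-exposed classes.
  # CI-exposed uninfected ova: those from infected mothers with infected
  # fathers (y_uninf) and those from uninfected mothers with infected
  # fathers ((N - I) * p, enumerated per-ovum).
  n_neg_mother_ci <- round((N - I) * p)
  surv_y_uninf <- if (y_uninf > 0) sum(runif(y_uninf) < 1 - sh) else 0
  surv_neg_ci <- if (n_neg_mother_ci > 0) sum(runif(n_neg_mother_ci) < 1 - sh) else 0
  # Unexposed classes: infected-offspring (y + z), uninfected ova from
  # infected mothers with uninfected fathers, uninfected mothers with
  # uninfected fathers.
  z_uninf <- sum(round(f_t * (1 - p) * r * I)) - z
  n_neg_mother_ok <- round((N - I) * (1 - p))
  total <- y + z + surv_y_uninf + surv_neg_ci + z_uninf + n_neg_mother_ok
  (y + z) / total
}

#' Compare empirical one-step moments with their analytic forms
#'
#' Draws `n_draws` independent one-step transitions from the engine at a
#' fixed state and compares the empirical mean and variance to the closed
#' forms (for `sh = 0`) or the deterministic projection as conditional mean
#' (for `sh > 0`, where the engine's deterministic CI thinning makes
#' [project_frequency()] the exact conditional mean up to trial rounding;
#' no closed-form variance is reported).
#'
#' @param params A [model_params()].
#' @param p Current frequency.
#' @param f_t Fitness value.
#' @param n_draws Number of independent one-step draws.
#' @return A one-row tibble: empirical and analytic mean and variance, their
#'   Monte-Carlo standard errors, and z-scores (`NA` where no analytic value
#'   applies).
#' @export
moment_check <- function(params, p, f_t, n_draws = 1e5) {
  stopifnot(inherits(params, "model_params"))
  I <- round(params$N * p)
  draws <- sample_offspring_frequency(p, I, params, f_t, n = n_draws)
  emp_mean <- mean(draws)
  emp_var <- sd(draws)^2
  se_mean <- sd(draws) / sqrt(n_draws)
  # SE of the sample variance via the fourth central moment
  m4 <- mean((draws - emp_mean)^4)
  se_var <- sqrt(max(m4 - emp_var^2, 0) / n_draws)
  if (params$sh == 0) {
    mom <- conditional_moments(p, params, f_t)
    ana_mean <- mom$mean
    ana_var <- mom$variance
  } else {
    ana_mean <- project_frequency(p, f_t, params$transmission$mu_bar, params$sh)
    ana_var <- NA_real_
  }
  tibble(
    p = p, f_t = f_t, n_draws = n_draws,
    empirical_mean = emp_mean, analytic_mean = ana_mean, se_mean = se_mean,
    z_mean = if (se_mean > 0) (emp_mean - ana_mean) / se_mean else NA_real_,
    empirical_var = emp_var, analytic_var = ana_var, se_var = se_var,
    z_var = if (!is.na(ana_var) && se_var > 0) (emp_var - ana_var) / se_var
            else NA_real_
  )
}

#' Empirical absorption-time profile
#'
#' Runs `n_runs` independent trajectories and records when (if ever) each is
#' absorbed at `p = 0`; a diagnostic of quasi-stationarity versus loss at
#' small population size.
#'
#' @param params A [model_params()].
#' @param protocol A [sim_protocol()]; `n_reps` is ignored in favour of
#'   `n_runs`.
#' @param n_runs Number of independent runs.
#' @return A tibble with one row per run: `run`, `seed`, `absorbed_at`
#'   (`NA` if never absorbed) and `absorbed` (logical). The fraction of runs
#'   absorbed by generation `t` is `mean(absorbed_at <= t, na.rm fixed)` on
#'   this table.
#' @export
absorption_profile <- function(params, protocol = sim_protocol(),
                               n_runs = 100L) {
  seeds <- derive_seeds(protocol$base_seed, n_runs)
  purrr::map_dfr(seq_len(n_runs), function(i) {
    traj <- simulate_trajectory(params, protocol, seed = seeds[i])
    ab <- attr(traj, "absorbed_at")
    tibble(
      run = i, seed = seeds[i],
      absorbed_at = as.integer(ab),
      absorbed = !is.na(ab)
    )
  })
}
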