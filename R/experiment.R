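#' Post-burn-in summary of a trajectory
#'
#' Computes the replicate summary statistics over generations
#' `burn_in + 1` through `T` inclusive (9,500 values under the default
#' protocol): the mean frequency `p_bar` and the sample standard deviation
#' `p_sd` (denominator `n - 1`), plus persistence flags.
#'
#' @param traj A [simulate_trajectory()] result, or any tibble with columns
#'   `generation` and `p`.
#' @param burn_in Generations discarded; defaults to the protocol recorded
#'   on the trajectory.
#' @return A one-row tibble with columns `p_bar`, `p_sd`, `persisted`
#'   (`p > 0` at the final generation) and `absorbed_at` (`NA` if never
#'   absorbed).
#' @export
summarize_trajectory <- function(traj, burn_in = NULL) {
  protocol <- attr(traj, "protocol")
  burn_in <- burn_in %||% protocol$burn_in
  if (is.null(burn_in)) {
    abort("`burn_in` must be given when the trajectory carries no protocol.")
  }
  T_gen <- max(traj$generation)
  if (burn_in >= T_gen) {
    abort("`burn_in`: summary window is empty (burn_in >= generations).")
  }
  window <- traj$p[traj$generation >= burn_in + 1]
  absorbed_at <- attr(traj, "absorbed_at")
  if (is.null(absorbed_at)) {
    zeros <- which(traj$p == 0)
    absorbed_at <- if (length(zeros)) traj$generation[zeros[1]] else NA_integer_
  }
  tibble(
    p_bar = mean(window),
    p_sd = sd(window),
    persisted = traj$p[traj$generation == T_gen] > 0,
    absorbed_at = as.integer(absorbed_at)
  )
}

#' Flag parameter sets whose deterministic prediction is loss
#'
#' A parameter combination is flagged when the deterministic model predicts
#' no interior stable equilibrium: the invasion condition
#' `F (1 - mu_bar) > 1` fails or the equilibrium solver finds no stable root
#' in `(0, 1]`. For fluctuating fitness, `F` is summarised by its median by
#' default; `rule = "mean"` uses the arithmetic mean
#' `E[F] = m * sqrt(cv^2 + 1)` instead (for a log-normal the geometric mean
#' equals the median, so the mean is the informative alternative summary).
#' Such combinations are excluded from equilibrium-focused analyses because
#' the infection is deterministically lost.
#'
#' @param params A [model_params()].
#' @param rule `"median"` (default) or `"mean"` fitness summary.
#' @return Logical: `TRUE` when loss is predicted.
#' @examples
#' flag_predicted_loss(model_params(1e4, 0.05, 1.05))  # TRUE
#' flag_predicted_loss(model_params(1e4, 0.001, 1.1))  # FALSE
#' @export
flag_predicted_loss <- function(params, rule = c("median", "mean")) {
  rule <- match.arg(rule)
  f <- fitness_summary(params$fitness, rule)
  mu <- params$transmission$mu_bar
  if (!invasion_condition(f, mu)) return(TRUE)
  eq <- equilibrium(params, fitness_rule = rule)
  !(is.finite(eq$p_hat) && eq$p_hat > 0 && eq$stability == "stable")
}

derive_seeds <- function(base_seed, n) {
  set.seed(base_seed)
  sample.int(.Machine$integer.max, n)
}

#' Run a replicate set and pool the summaries
#'
#' Simulates `protocol$n_reps` independent trajectories, each under its own
#' seed derived from `protocol$base_seed`, trims the burn-in, and pools the
#' per-replicate statistics: `p_dbar` is the mean of the per-replicate means
#' and `p_sd_bar` the mean of the per-replicate standard deviations. The
#' whole set is reproducible from the base seed alone.
#'
#' @param params A [model_params()].
#' @param protocol A [sim_protocol()].
#' @param adult_resampling Passed to [simulate_trajectory()].
#' @return An object of class `symdrift_replicates`: use [tidy()] for the
#'   per-replicate table (columns `replicate`, `seed`, `p_bar`, `p_sd`,
#'   `persisted`, `absorbed_at`) and [glance()] for the one-row pooled
#'   summary.
#' @examples
#' pars <- model_params(1e3, 0.001, 1.1)
#' reps <- run_replicates(pars, sim_protocol(generations = 600, n_reps = 4,
#'                                           base_seed = 7))
#' glance(reps)
#' @export
run_replicates <- function(params, protocol = sim_protocol(),
                           adult_resampling = FALSE) {
  stopifnot(inherits(params, "model_params"), inherits(protocol, "sim_protocol"))
  seeds <- derive_seeds(protocol$base_seed, protocol$n_reps)
  records <- purrr::map_dfr(seq_len(protocol$n_reps), function(i) {
    traj <- simulate_trajectory(params, protocol, seed = seeds[i],
                                adult_resampling = adult_resampling)
    dplyr::bind_cols(
      tibble(replicate = i, seed = seeds[i]),
      summarize_trajectory(traj)
    )
  })
  pooled <- tibble(
    n_reps = protocol$n_reps,
    p_dbar = mean(records$p_bar),
    p_sd_bar = mean(records$p_sd),
    n_persisted = sum(records$persisted)
  )
  structure(
    list(replicates = records, pooled = pooled, params = params,
         protocol = protocol),
    class = "symdrift_replicates"
  )
}

#' @export
print.symdrift_replicates <- function(x, ...) {
  cat("<symdrift_replicates>", x$pooled$n_reps, "replicates\n")
  print(x$params)
  cat(
    "  pooled mean p_dbar =", format(x$pooled$p_dbar),
    "  mean SD p_sd_bar =", format(x$pooled$p_sd_bar),
    "  persisted:", x$pooled$n_persisted, "/", x$pooled$n_reps, "\n"
  )
  invisible(x)
}

#' @method tidy symdrift_replicates
#' @export
tidy.symdrift_replicates <- function(x, ...) {
  x$replicates
}

#' @method glance symdrift_replicates
#' @export
glance.symdrift_replicates <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      N = x$params$N, sh = x$params$sh,
      mu_bar = x$params$transmission$mu_bar,
      fitness_median = x$params$fitness$median,
      fitness_cv = x$params$fitness$cv,
      base_seed = x$protocol$base_seed
    ),
    x$pooled
  )
}

#' Build a parameter grid
#'
#' Cartesian product of parameter axes as a tibble, one row per
#' combination, ready for [run_grid()]. The default axes span the
#' biologically plausible ranges commonly explored for *Wolbachia*-like
#' symbionts in *Drosophila*.
#'
#' @param N Population sizes.
#' @param mu Main-group transmission-failure rates.
#' @param fitness Fitness medians.
#' @param sh CI strengths.
#' @param cv Fitness coefficients of variation (0 = fixed fitness).
#' @param low_transmitters Logical: include a low-transmitter subgroup.
#' @return A tibble with one row per combination.
#' @export
param_grid <- function(N = 10^(3:6),
                       mu = c(0.001, 0.01, 0.05, 0.1, 0.2, 0.3),
                       fitness = c(1.0, 1.025, 1.05, 1.1, 1.2, 1.3, 1.5),
                       sh = c(0, 0.1, 0.45),
                       cv = 0,
                       low_transmitters = FALSE) {
  tidyr::crossing(
    N = N, mu = mu, fitness = fitness, sh = sh, cv = cv,
    low_transmitters = low_transmitters
  )
}

grid_row_params <- function(row, lt_fraction, lt_mu) {
  transmission <- if (isTRUE(row$low_transmitters)) {
    low_transmitter_profile(row$mu, lt_fraction, lt_mu)
  } else {
    transmission_profile(row$mu)
  }
  model_params(
    N = row$N,
    transmission = transmission,
    fitness = fitness_spec(row$fitness, cv = row$cv),
    sh = row$sh
  )
}

#' Run replicate sets over a parameter grid
#'
#' Takes a grid of parameter combinations (one row each; see
#' [param_grid()]), runs a full replicate set per row, and returns a
#' long-format pooled summary in the input row order. Each row gets its own
#' base seed derived deterministically from `protocol$base_seed`, logged in
#' the output. Rows whose deterministic prediction is loss are flagged, not
#' dropped; replicates that happen to be absorbed are likewise retained and
#' counted in `n_persisted`.
#'
#' @param grid A data frame with columns `N`, `mu`, `fitness`, `sh` and
#'   optionally `cv` (default 0) and `low_transmitters` (default `FALSE`).
#' @param protocol A [sim_protocol()] applied to every row.
#' @param lt_fraction,lt_mu Low-transmitter subgroup configuration used for
#'   rows with `low_transmitters = TRUE` (defaults: 10% of infected females
#'   at `mu = 0.8`).
#' @param per_replicate If `TRUE`, attach the per-replicate tables as a
#'   list-column `replicates`.
#' @param cap Refuse grids with more combinations than this.
#' @param adult_resampling Passed to [simulate_trajectory()].
#' @return A tibble with one row per combination: the axes, `mu_bar`,
#'   pooled statistics (`p_dbar`, `p_sd_bar`, `n_persisted`, `n_reps`),
#'   predicted-loss flags under both fitness summaries, and `base_seed`.
#' @export
run_grid <- function(grid, protocol = sim_protocol(), lt_fraction = 0.1,
                     lt_mu = 0.8, per_replicate = FALSE, cap = 2000L,
                     adult_resampling = FALSE) {
  grid <- as_tibble(grid)
  required <- c("N", "mu", "fitness", "sh")
  missing_cols <- setdiff(required, names(grid))
  if (length(missing_cols)) {
    abort(paste0("`grid` lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(grid) == 0) abort("`grid` has no rows.")
  if (nrow(grid) > cap) {
    abort(sprintf("`grid` has %d combinations, above the cap of %d.",
                  nrow(grid), cap))
  }
  if (!"cv" %in% names(grid)) grid$cv <- 0
  if (!"low_transmitters" %in% names(grid)) grid$low_transmitters <- FALSE

  row_seeds <- derive_seeds(protocol$base_seed, nrow(grid))
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    params <- grid_row_params(row, lt_fraction, lt_mu)
    row_protocol <- protocol
    row_protocol$base_seed <- row_seeds[i]
    reps <- run_replicates(params, row_protocol,
                           adult_resampling = adult_resampling)
    res <- dplyr::bind_cols(
      row,
      tibble(
        mu_bar = params$transmission$mu_bar,
        predicted_loss = flag_predicted_loss(params),
        predicted_loss_mean_f = flag_predicted_loss(params, rule = "mean"),
        base_seed = row_seeds[i]
      ),
      reps$pooled
    )
    if (per_replicate) res$replicates <- list(reps$replicates)
    res
  })
  out
}
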