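#' Maternal transmission profile
#'
#' Describes imperfect maternal transmission of the endosymbiont, optionally
#' split into subgroups of infected females with distinct failure rates. Each
#' subgroup `i` comprises a fraction `r_i` of infected females whose ova are
#' uninfected with probability `mu_i`. The homogeneous model is the one-group
#' special case; there is no separate code path for it.
#'
#' @param mu Numeric vector of transmission-failure probabilities, one per
#'   subgroup, each in `[0, 1]`. `mu` is the probability that an infected
#'   mother produces an uninfected ovum.
#' @param fraction Numeric vector of subgroup fractions summing to 1. Defaults
#'   to a single group when `mu` has length 1.
#' @return An object of class `transmission_profile` with elements `groups`
#'   (a tibble with columns `fraction`, `mu`) and `mu_bar`, the population
#'   mean failure rate `sum(fraction * mu)`.
#' @examples
#' transmission_profile(0.05)
#' # 10% low transmitters at mu = 0.8, remainder nearly perfect:
#' transmission_profile(mu = c(0.001, 0.8), fraction = c(0.9, 0.1))
#' @seealso [low_transmitter_profile()]
#' @export
transmission_profile <- function(mu, fraction = NULL) {
  if (is.null(fraction)) {
    if (length(mu) != 1L) {
      abort("`fraction` must be supplied when `mu` has more than one group.")
    }
    fraction <- 1
  }
  if (length(fraction) != length(mu)) {
    abort("`transmission.groups`: `fraction` and `mu` must have equal length.")
  }
  if (!is.numeric(mu) || anyNA(mu) || any(mu < 0) || any(mu > 1)) {
    abort("`transmission.groups`: every `mu` must lie in [0, 1].")
  }
  if (!is.numeric(fraction) || anyNA(fraction) || any(fraction < 0)) {
    abort("`transmission.groups`: every `fraction` must be non-negative.")
  }
  if (abs(sum(fraction) - 1) > 1e-12) {
    abort(sprintf(
      "`transmission.groups`: fractions must sum to 1 (got %.15g).",
      sum(fraction)
    ))
  }
  structure(
    list(
      groups = tibble(fraction = as.numeric(fraction), mu = as.numeric(mu)),
      mu_bar = sum(fraction * mu)
    ),
    class = "transmission_profile"
  )
}

#' Transmission profile with a low-transmitter subgroup
#'
#' Convenience constructor for the configuration in which most infected
#' females transmit well but a minority ("low transmitters") have a high
#' failure rate, as reported for several field-collected *Drosophila*
#' systems. Defaults follow the commonly used configuration of 10% of
#' infected females at `mu = 0.8`.
#'
#' @param mu Failure rate of the main (well-transmitting) subgroup.
#' @param lt_fraction Fraction of infected females that are low transmitters.
#' @param lt_mu Failure rate of the low-transmitter subgroup.
#' @return A [transmission_profile()].
#' @export
low_transmitter_profile <- function(mu, lt_fraction = 0.1, lt_mu = 0.8) {
  transmission_profile(
    mu = c(mu, lt_mu),
    fraction = c(1 - lt_fraction, lt_fraction)
  )
}

#' @export
print.transmission_profile <- function(x, ...) {
  cat("<transmission_profile> mu_bar =", format(x$mu_bar), "\n")
  print(x$groups)
  invisible(x)
}

#' Relative fitness specification
#'
#' Relative fecundity `F` of infected females, either fixed or drawn each
#' generation from a log-normal distribution with a given median `m` and
#' coefficient of variation. For the log-normal mode, `F = exp(X)` with
#' `X ~ Normal(mu_x, sigma^2)`, `mu_x = log(m)` and
#' `sigma^2 = log(cv^2 + 1)`, so that `m` is the median of `F` and `cv` its
#' coefficient of variation. `cv = 0` degenerates exactly to the fixed case.
#'
#' @param median Median (fixed mode: the value) of relative fecundity, > 0.
#' @param cv Coefficient of variation of per-generation fitness draws, >= 0.
#' @param mode `"fixed"` or `"lognormal"`; inferred from `cv` when `NULL`.
#' @return An object of class `fitness_spec` with fields `mode`, `median`,
#'   `cv` and derived log-scale parameters `mu_x`, `sigma`.
#' @examples
#' fitness_spec(1.1)
#' fitness_spec(1.025, cv = 0.1)
#' @export
fitness_spec <- function(median, cv = 0, mode = NULL) {
  if (!is.numeric(median) || length(median) != 1L || is.na(median) ||
      median <= 0) {
    abort("`fitness.median`: relative fecundity must be a single value > 0.")
  }
  if (!is.numeric(cv) || length(cv) != 1L || is.na(cv) || cv < 0) {
    abort("`fitness.cv`: coefficient of variation must be >= 0.")
  }
  mode <- mode %||% if (cv > 0) "lognormal" else "fixed"
  mode <- match.arg(mode, c("fixed", "lognormal"))
  if (mode == "fixed" && cv > 0) {
    abort("`fitness.cv`: must be 0 when mode is \"fixed\".")
  }
  structure(
    list(
      mode = mode,
      median = as.numeric(median),
      cv = as.numeric(cv),
      mu_x = log(median),
      sigma = sqrt(log(cv^2 + 1))
    ),
    class = "fitness_spec"
  )
}

#' @export
print.fitness_spec <- function(x, ...) {
  cat(
    "<fitness_spec>", x$mode, "median =", format(x$median),
    if (x$mode == "lognormal") paste("cv =", format(x$cv)) else "", "\n"
  )
  invisible(x)
}

#' Quantiles of the per-generation fitness distribution
#'
#' Closed-form quantiles of the log-normal fitness distribution (degenerate
#' at the median in fixed mode): `q(p) = m * exp(z_p * sigma)` with `z_p` the
#' standard-normal quantile.
#'
#' @param spec A [fitness_spec()].
#' @param probs Probabilities.
#' @return Numeric vector of quantiles.
#' @examples
#' fitness_quantile(fitness_spec(1.05, cv = 0.01), c(0.025, 0.975))
#' @export
fitness_quantile <- function(spec, probs = c(0.025, 0.975)) {
  stopifnot(inherits(spec, "fitness_spec"))
  if (spec$mode == "fixed" || spec$sigma == 0) {
    return(rep(spec$median, length(probs)))
  }
  spec$median * exp(stats::qnorm(probs) * spec$sigma)
}

#' Model parameters for a finite host population
#'
#' Bundles the female effective population size `N`, the strength of
#' cytoplasmic incompatibility `sh` (relative hatch `H = 1 - sh` of
#' uninfected ova fertilised by infected males), a [transmission_profile()]
#' and a [fitness_spec()].
#'
#' Complete incompatibility (`sh = 1`) is rejected by default; the dynamics
#' studied with this package live in the `sh < 1` regime and `sh = 1`
#' degenerates the recursion. Set `allow_complete_ci = TRUE` to explore it
#' anyway.
#'
#' @param N Positive integer female effective population size.
#' @param transmission A [transmission_profile()], or a single `mu` value as
#'   shorthand for a homogeneous profile.
#' @param fitness A [fitness_spec()], or a single fixed `F` value.
#' @param sh CI strength in `[0, 1)`.
#' @param allow_complete_ci Permit `sh = 1` (off by default).
#' @return An object of class `model_params` with derived hatch `H = 1 - sh`.
#' @examples
#' model_params(N = 1e4, transmission = 0.001, fitness = 1.1)
#' @export
model_params <- function(N, transmission, fitness, sh = 0,
                         allow_complete_ci = FALSE) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 ||
      N != floor(N)) {
    abort("`N`: population size must be a positive integer (N >= 1).")
  }
  sh_max_ok <- if (allow_complete_ci) sh <= 1 else sh < 1
  if (!is.numeric(sh) || length(sh) != 1L || is.na(sh) || sh < 0 ||
      !sh_max_ok) {
    abort("`sh`: CI strength must lie in [0, 1).")
  }
  if (is.numeric(transmission)) transmission <- transmission_profile(transmission)
  if (!inherits(transmission, "transmission_profile")) {
    abort("`transmission` must be a transmission_profile or a single mu value.")
  }
  if (is.numeric(fitness)) fitness <- fitness_spec(fitness)
  if (!inherits(fitness, "fitness_spec")) {
    abort("`fitness` must be a fitness_spec or a single fixed value.")
  }
  structure(
    list(
      N = as.integer(N),
      sh = as.numeric(sh),
      H = 1 - as.numeric(sh),
      transmission = transmission,
      fitness = fitness
    ),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(
    "<model_params> N =", x$N, " sh =", format(x$sh),
    " mu_bar =", format(x$transmission$mu_bar),
    " F:", x$fitness$mode, format(x$fitness$median),
    if (x$fitness$mode == "lognormal") paste0("(cv ", x$fitness$cv, ")") else "",
    "\n"
  )
  invisible(x)
}

#' Simulation protocol
#'
#' Protocol for replicate stochastic runs: initial frequency, run length,
#' burn-in discarded before summarising, replicate count, and the base seed
#' from which per-replicate seeds are derived. Defaults match the standard
#' batch protocol: `p0 = 0.4`, 10,000 generations, 500 generations burn-in,
#' 25 replicates.
#'
#' @param p0 Initial infection frequency in `[0, 1]`.
#' @param generations Total generations simulated, >= 1.
#' @param burn_in Generations discarded before summarising,
#'   `0 <= burn_in < generations`.
#' @param n_reps Number of replicate simulations, >= 1.
#' @param base_seed Integer seed; per-replicate streams derive from it.
#' @return An object of class `sim_protocol`.
#' @export
sim_protocol <- function(p0 = 0.4, generations = 10000L, burn_in = 500L,
                         n_reps = 25L, base_seed = 1L) {
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 < 0 || p0 > 1) {
    abort("`p0`: initial frequency must lie in [0, 1].")
  }
  if (!is.numeric(generations) || generations < 1 ||
      generations != floor(generations)) {
    abort("`generations`: must be a positive integer.")
  }
  if (!is.numeric(burn_in) || burn_in < 0 || burn_in != floor(burn_in) ||
      burn_in >= generations) {
    abort("`burn_in`: must satisfy 0 <= burn_in < generations.")
  }
  if (!is.numeric(n_reps) || n_reps < 1 || n_reps != floor(n_reps)) {
    abort("`n_reps`: replicate count must be a positive integer.")
  }
  if (!is.numeric(base_seed) || length(base_seed) != 1L || is.na(base_seed)) {
    abort("`base_seed`: must be a single integer.")
  }
  structure(
    list(
      p0 = as.numeric(p0),
      generations = as.integer(generations),
      burn_in = as.integer(burn_in),
      n_reps = as.integer(n_reps),
      base_seed = as.integer(base_seed)
    ),
    class = "sim_protocol"
  )
}

#' @export
print.sim_protocol <- function(x, ...) {
  cat(
    "<sim_protocol> p0 =", x$p0, " generations =", x$generations,
    " burn_in =", x$burn_in, " n_reps =", x$n_reps,
    " base_seed =", x$base_seed, "\n"
  )
  invisible(x)
}

#' Population state
#'
#' Snapshot of the engine state at one generation: the infection frequency
#' `p` and the infected female count `I = round(N * p)`. `p = 0` if and only
#' if `I = 0`, and loss is absorbing.
#'
#' @param p Infection frequency in `[0, 1]`.
#' @param N Female population size.
#' @param t Generation index, >= 0.
#' @return An object of class `population_state` with fields `t`, `p`, `I`.
#' @export
population_state <- function(p, N, t = 0L) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort("`p`: frequency must lie in [0, 1].")
  }
  I <- round(N * p)
  if (I == 0) p <- 0
  structure(list(t = as.integer(t), p = as.numeric(p), I = as.numeric(I)),
            class = "population_state")
}

#' Validate a parameter/protocol pair
#'
#' Revalidates every invariant of a [model_params()] and [sim_protocol()]
#' pair (fractions summing to one, rates in range, burn-in shorter than the
#' run) and returns the pair with all derived fields recomputed from primary
#' fields. Errors name the offending field.
#'
#' @param params A [model_params()].
#' @param protocol A [sim_protocol()].
#' @return Invisibly, `list(params = , protocol = )` with derived fields
#'   (`mu_bar`, `H`, `mu_x`, `sigma`) freshly recomputed.
#' @export
validate_params <- function(params, protocol = sim_protocol()) {
  if (!inherits(params, "model_params")) abort("`params` must be a model_params object.")
  if (!inherits(protocol, "sim_protocol")) abort("`protocol` must be a sim_protocol object.")
  params <- model_params(
    N = params$N,
    transmission = transmission_profile(
      mu = params$transmission$groups$mu,
      fraction = params$transmission$groups$fraction
    ),
    fitness = fitness_spec(params$fitness$median, params$fitness$cv,
                           params$fitness$mode),
    sh = params$sh,
    allow_complete_ci = TRUE
  )
  protocol <- sim_protocol(
    p0 = protocol$p0, generations = protocol$generations,
    burn_in = protocol$burn_in, n_reps = protocol$n_reps,
    base_seed = protocol$base_seed
  )
  invisible(list(params = params, protocol = protocol))
}

# Median or mean summary of the fitness spec, used where a single F value
# stands in for a fluctuating one (equilibria, loss prediction).
fitness_summary <- function(spec, rule = c("median", "mean")) {
  rule <- match.arg(rule)
  if (rule == "median") spec$median else spec$median * sqrt(spec$cv^2 + 1)
}
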