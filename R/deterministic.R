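#' One generation of the deterministic frequency recursion
#'
#' Infinite-population recursion for the adult infection frequency under
#' imperfect maternal transmission (`mu`), relative fecundity of infected
#' females (`fitness`), and cytoplasmic incompatibility (`sh`):
#'
#' \deqn{p' = \frac{p F (1-\mu)}{1 + p(F - 1 - s_h) + p^2 s_h (1 - \mu F)}}
#'
#' With `sh = 0` this reduces to `p F (1 - mu) / (1 + p (F - 1))`. For a
#' multi-group transmission profile, `mu` is the population mean failure
#' rate.
#'
#' @param p Frequency (vectorised) in `[0, 1]`.
#' @param fitness Relative fecundity `F > 0` of infected females.
#' @param mu Mean transmission-failure rate in `[0, 1]`.
#' @param sh CI strength in `[0, 1)`.
#' @return Next-generation frequency, in `[0, 1]`.
#' @examples
#' project_frequency(0.4, fitness = 1.1, mu = 0.001)
#' @export
project_frequency <- function(p, fitness, mu, sh = 0) {
  stopifnot(
    all(p >= 0 & p <= 1), fitness > 0,
    mu >= 0, mu <= 1, sh >= 0, sh < 1
  )
  denom <- 1 + p * (fitness - 1 - sh) + p^2 * sh * (1 - mu * fitness)
  if (any(denom <= 0)) {
    abort("project_frequency: non-positive denominator; inputs outside the valid domain.")
  }
  pmin(pmax(p * fitness * (1 - mu) / denom, 0), 1)
}

# d(map)/dp. Analytic for sh = 0; central finite difference otherwise.
map_derivative <- function(p, fitness, mu, sh = 0, h = 1e-7) {
  if (sh == 0) {
    return(fitness * (1 - mu) / (1 + p * (fitness - 1))^2)
  }
  lo <- max(p - h, 0)
  hi <- min(p + h, 1)
  (project_frequency(hi, fitness, mu, sh) -
      project_frequency(lo, fitness, mu, sh)) / (hi - lo)
}

#' Deterministic invasion condition
#'
#' An initially rare endosymbiont spreads deterministically if and only if
#' `F (1 - mu) > 1` (strict), regardless of CI strength.
#'
#' @inheritParams project_frequency
#' @return Logical.
#' @examples
#' invasion_condition(1.1, 0.001)
#' invasion_condition(1.0, 0)   # boundary: FALSE
#' @export
invasion_condition <- function(fitness, mu) {
  stopifnot(fitness > 0, mu >= 0, mu <= 1)
  fitness * (1 - mu) > 1
}

new_equilibrium <- function(p_hat, stability, roots, fitness, mu, sh) {
  structure(
    list(
      p_hat = p_hat, stability = stability, all_roots = roots,
      fitness = fitness, mu = mu, sh = sh,
      invasion = invasion_condition(fitness, mu)
    ),
    class = "symdrift_equilibrium"
  )
}

#' @export
print.symdrift_equilibrium <- function(x, ...) {
  cat(
    "<symdrift_equilibrium> p_hat =",
    if (is.na(x$p_hat)) "none" else format(x$p_hat),
    " stability =", x$stability,
    " invasion =", x$invasion, "\n"
  )
  invisible(x)
}

#' Equilibrium frequency without cytoplasmic incompatibility
#'
#' With `sh = 0` and the invasion condition `F (1 - mu) > 1` satisfied, the
#' recursion has the interior stable fixed point
#' \deqn{\hat p = 1 - \frac{\mu F}{F - 1},}
#' with `mu` the (mean) transmission-failure rate. If the invasion condition
#' fails, no interior equilibrium exists and the result reports
#' `stability = "none"`.
#'
#' @inheritParams project_frequency
#' @return A `symdrift_equilibrium`: `p_hat` (NA when absent), `stability`
#'   (`"stable"`, `"unstable"`, `"none"`), `all_roots` of the fixed-point
#'   equation, and the invasion flag.
#' @examples
#' equilibrium_no_ci(1.1, 0.001)   # p_hat = 0.989
#' equilibrium_no_ci(1.1, 0.0809)  # low-transmitter mean: p_hat = 0.1101
#' @export
equilibrium_no_ci <- function(fitness, mu) {
  stopifnot(fitness > 0, mu >= 0, mu <= 1)
  if (fitness == 1) {
    # 1 - mu*F/(F-1) undefined; interior equilibrium only if mu = 0 (neutral).
    return(new_equilibrium(NA_real_, "none", numeric(0), fitness, mu, 0))
  }
  root <- 1 - mu * fitness / (fitness - 1)
  if (!invasion_condition(fitness, mu)) {
    # At the exact invasion boundary F = 1/(1 - mu) the root collapses to 0.
    if (abs(root) <= 1e-12) {
      return(new_equilibrium(0, classify_stability(0, fitness, mu, 0),
                             0, fitness, mu, 0))
    }
    return(new_equilibrium(NA_real_, "none", root, fitness, mu, 0))
  }
  if (root < 0 || root > 1) {
    return(new_equilibrium(NA_real_, "none", root, fitness, mu, 0))
  }
  stability <- classify_stability(root, fitness, mu, sh = 0)
  new_equilibrium(root, stability, root, fitness, mu, 0)
}

#' Equilibrium frequency with cytoplasmic incompatibility
#'
#' Fixed points of the full recursion solve the quadratic
#' \deqn{s_h (1 - F\mu) p^2 + (F - 1 - s_h) p + 1 - F(1 - \mu) = 0.}
#' When `F (1 - mu) > 1` and `F mu < 1`, the branch
#' \deqn{\hat p = \frac{s_h + 1 - F + \sqrt{(s_h + 1 - F)^2 +
#'   4 s_h (F(1-\mu) - 1)(1 - F\mu)}}{2 s_h (1 - F\mu)}}
#' is the single interior stable equilibrium. The returned root is always
#' verified to be a fixed point and classified through the map derivative
#' rather than trusted from sign analysis. When the quadratic degenerates
#' (`2 sh (1 - F mu)` below `1e-12`, i.e. `sh -> 0` or `F mu -> 1`), the
#' exact linear-root limit `(F(1-mu) - 1) / (F - 1 - sh)` is used, which
#' coincides with [equilibrium_no_ci()] as `sh -> 0`.
#'
#' @inheritParams project_frequency
#' @return A `symdrift_equilibrium`; `stability = "none"` with `p_hat = NA`
#'   when the discriminant is negative or no root lies in `[0, 1]`.
#' @examples
#' equilibrium_ci(1.05, 0.05, sh = 0.45)
#' @export
equilibrium_ci <- function(fitness, mu, sh) {
  stopifnot(fitness > 0, mu >= 0, mu <= 1, sh >= 0, sh < 1)
  a <- sh * (1 - fitness * mu)
  b <- fitness - 1 - sh
  cc <- 1 - fitness * (1 - mu)
  if (abs(2 * a) < 1e-12) {
    if (abs(b) < 1e-12) {
      return(new_equilibrium(NA_real_, "none", numeric(0), fitness, mu, sh))
    }
    root <- -cc / b
    roots <- root
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) {
      return(new_equilibrium(NA_real_, "none", numeric(0), fitness, mu, sh))
    }
    roots <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
    root <- roots[2]  # "+ sqrt" branch
  }
  in_unit <- root >= -1e-12 && root <= 1 + 1e-12
  if (!in_unit) {
    return(new_equilibrium(NA_real_, "none", roots, fitness, mu, sh))
  }
  root <- min(max(root, 0), 1)
  resid <- abs(project_frequency(root, fitness, mu, sh) - root)
  if (resid > 1e-8) {
    return(new_equilibrium(NA_real_, "none", roots, fitness, mu, sh))
  }
  stability <- classify_stability(root, fitness, mu, sh)
  new_equilibrium(root, stability, roots, fitness, mu, sh)
}

#' Stability of a fixed point of the deterministic map
#'
#' Classifies a fixed point by the magnitude of the map derivative: stable
#' iff `|d p'/d p| < 1`. The derivative is analytic for `sh = 0`
#' (`F (1 - mu) / (1 + p (F - 1))^2`) and a central finite difference with
#' step `1e-7` otherwise. A derivative magnitude within `1e-9` of 1 is
#' treated conservatively as unstable (marginal case).
#'
#' @param p A fixed point of [project_frequency()] (residual <= 1e-8).
#' @inheritParams project_frequency
#' @return `"stable"` or `"unstable"`.
#' @examples
#' classify_stability(0, 1.1, 0.001)            # unstable: invasion holds
#' classify_stability(0.989, 1.1, 0.001)        # stable interior point
#' @export
classify_stability <- function(p, fitness, mu, sh = 0) {
  resid <- abs(project_frequency(p, fitness, mu, sh) - p)
  if (resid > 1e-8) {
    abort(sprintf(
      "classify_stability: p = %.10g is not a fixed point (residual %.3g > 1e-8).",
      p, resid
    ))
  }
  d <- abs(map_derivative(p, fitness, mu, sh))
  if (abs(d - 1) <= 1e-9) return("unstable")  # marginal, conservative
  if (d < 1) "stable" else "unstable"
}

#' Equilibrium for a full parameter set
#'
#' Dispatches to [equilibrium_no_ci()] or [equilibrium_ci()] using the mean
#' transmission-failure rate of the profile and a single summary of the
#' fitness spec (its median by default; the arithmetic mean optionally).
#'
#' @param params A [model_params()].
#' @param fitness_rule Summary used for fluctuating fitness: `"median"`
#'   (default) or `"mean"` (`E[F] = m * sqrt(cv^2 + 1)`).
#' @return A `symdrift_equilibrium`.
#' @export
equilibrium <- function(params, fitness_rule = c("median", "mean")) {
  stopifnot(inherits(params, "model_params"))
  f <- fitness_summary(params$fitness, match.arg(fitness_rule))
  mu <- params$transmission$mu_bar
  if (params$sh == 0) equilibrium_no_ci(f, mu) else equilibrium_ci(f, mu, params$sh)
}

#' Iterate the deterministic recursion
#'
#' @param p0 Initial frequency in `[0, 1]`.
#' @inheritParams project_frequency
#' @param generations Number of generations to iterate, >= 1.
#' @return A tibble with columns `generation` (0..generations) and `p`.
#' @examples
#' traj <- iterate_deterministic(0.4, fitness = 1.1, mu = 0.001,
#'                               generations = 200)
#' tail(traj)
#' @export
iterate_deterministic <- function(p0, fitness, mu, sh = 0,
                                  generations = 10000L) {
  stopifnot(p0 >= 0, p0 <= 1, generations >= 1)
  p <- numeric(generations + 1)
  p[1] <- p0
  for (t in seq_len(generations)) {
    p[t + 1] <- project_frequency(p[t], fitness, mu, sh)
  }
  tibble(generation = 0:generations, p = p)
}

#' @method tidy symdrift_equilibrium
#' @export
tidy.symdrift_equilibrium <- function(x, ...) {
  if (length(x$all_roots) == 0) {
    return(tibble(root = numeric(0), in_unit_interval = logical(0)))
  }
  tibble(
    root = x$all_roots,
    in_unit_interval = x$all_roots >= 0 & x$all_roots <= 1
  )
}

#' @method glance symdrift_equilibrium
#' @export
glance.symdrift_equilibrium <- function(x, ...) {
  tibble(
    p_hat = x$p_hat, stability = x$stability, invasion = x$invasion,
    fitness = x$fitness, mu = x$mu, sh = x$sh
  )
}
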