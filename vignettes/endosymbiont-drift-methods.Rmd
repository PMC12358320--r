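---
title: "Modelling stochastic endosymbiont frequency dynamics with symdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stochastic endosymbiont frequency dynamics with symdrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`symdrift` models the population frequency of a facultative, maternally
transmitted endosymbiont (the motivating case is *Wolbachia* in
*Drosophila*) in a finite host population with discrete, non-overlapping
generations. This vignette is the package's account of the model, its
assumptions, the numerical choices behind the implementation, and what the
test suite does and does not establish.

## The deterministic skeleton

Three parameters govern the dynamics:

| parameter | meaning | units | plausible range |
|---|---|---|---|
| `mu` | probability an infected mother produces an uninfected ovum | probability | 0.001–0.3 (field and lab estimates) |
| `fitness` (`F`) | fecundity of infected relative to uninfected females | dimensionless ratio | 1–1.5; benefits above ~1.2 undocumented |
| `sh` | hatch reduction of uninfected ova fertilised by infected males (CI) | proportion | 0 (none), ~0.1 (weak), ~0.45 (strong) |

Partitioning one generation's offspring by the infection status of both
parents, weighting infected mothers' ova by `F`, removing a fraction `mu`
of their ova to transmission failure, and thinning CI-exposed uninfected
ova by `1 - sh` gives the recursion implemented in `project_frequency()`:

$$p' = \frac{p F (1-\mu)}{1 + p(F - 1 - s_h) + p^2 s_h (1 - \mu F)}.$$

Key consequences, each carried by a dedicated function:

- **Invasion** (`invasion_condition()`): a rare symbiont spreads iff
  $F(1-\mu) > 1$, with or without CI, because CI confers no advantage when
  infected males are rare.
- **Equilibrium without CI** (`equilibrium_no_ci()`):
  $\hat p = 1 - \mu F / (F-1)$, balancing the fecundity benefit against
  transmission leakage. With a heterogeneous transmission profile the same
  formula holds with the population mean $\bar\mu = \sum_i r_i \mu_i$.
- **Equilibrium with CI** (`equilibrium_ci()`): fixed points solve
  $s_h(1-F\mu)p^2 + (F-1-s_h)p + 1 - F(1-\mu) = 0$; the `+√` branch is the
  interior stable point when $F(1-\mu) > 1$ and $F\mu < 1$.
- **Stability** (`classify_stability()`): by the magnitude of the map
  derivative at the fixed point.

## The stochastic engine

Finite population size enters through binomial sampling of offspring
infection status, analogous to a haploid Wright–Fisher model with an
effective population of `N` females ($I_t = N p_t$ of them infected;
males are assumed infected at the same frequency). Per transmission
subgroup `i`:

- no CI: $X_i \sim \mathrm{Bin}(F_t r_i I,\, 1-\mu_i)$ and
  $p' = (\sum_i X_i / N) / (p(F_t - 1) + 1)$;
- CI: infected offspring are drawn separately for infected and uninfected
  fathers, $Y_i \sim \mathrm{Bin}(F_t\, p\, r_i I, 1-\mu_i)$ and
  $Z_i \sim \mathrm{Bin}(F_t (1-p) r_i I, 1-\mu_i)$, and the denominator
  adds the (deterministically thinned) surviving uninfected classes:
  $p' = (\tilde X_1 + \tilde X_2) / (s_h(1-F_t)p^2 + (F_t - s_h - 1)p +
  s_h \tilde X_1 + 1)$ with $\tilde X_k = X_k / N$.

The closed-form conditional moments for the no-CI step
(`conditional_moments()`) are
$E[p'|p] = F(1-\bar\mu)p/(p(F-1)+1)$ and
$\mathrm{Var}[p'|p] = p \sum_i F r_i \mu_i (1-\mu_i) / (N (p(F-1)+1)^2)$,
the latter by additivity of the independent per-subgroup binomial
variances. As $N \to \infty$ the variance vanishes and the stochastic
recursion converges on `project_frequency()` — a property the tests check
directly at $N = 10^7$.

Numerical and structural choices, in decreasing order of consequence:

- **Where the randomness lives.** All randomness is placed in offspring
  infection status; the next adult count is $I' = \mathrm{round}(N p')$.
  The variance formula above is exact only under this reading. The
  alternative reading — an additional adult-sampling stage
  $I' \sim \mathrm{Bin}(N, p')$ — is available as
  `simulate_trajectory(adult_resampling = TRUE)` for comparison; it adds
  classic Wright–Fisher sampling noise on top of the offspring noise and
  is *not* the default.
- **CI mortality is deterministic thinning**, a factor $1-s_h$ applied to
  the CI-exposed uninfected classes in the denominator, not per-ovum
  Bernoulli survival. The individual-based oracle (`oracle_step_ci()`)
  mirrors this so that it validates exactly the recursion the engine
  implements; a `ci_bernoulli = TRUE` variant exists purely for
  sensitivity exploration.
- **Fractional binomial trial counts** ($F r_i I$ is generically
  non-integer) are rounded half to even once per draw. This is unbiased
  across a parameter grid and preserves the conditional moments to
  $O(1/N)$; moment-matching tests therefore pin states where the trial
  counts are exact integers.
- **Absorption.** `p = 0` iff `I = 0`, so a projected frequency below
  $1/(2N)$ rounds to the absorbed state. Loss is absorbing; fixation is
  not when `mu > 0`.
- **One fitness draw per generation**, shared by all females and feeding
  both numerator and denominator of that generation's recursion. With
  log-normal fitness, `F = exp(X)`, $X \sim N(\ln m, \ln(CV^2+1))$, so `m`
  is the median and `CV` the coefficient of variation; `CV = 0`
  degenerates exactly to fixed fitness.

## Equilibrium numerics

- The `+√` quadratic branch is never trusted blindly: the root is checked
  to lie in $[0,1]$, verified as a fixed point to residual $10^{-12}$, and
  classified through the map derivative.
- When the quadratic's leading coefficient degenerates
  ($2 s_h (1 - F\mu) < 10^{-12}$, reachable via $s_h \to 0$ or
  $F\mu \to 1$), the solver switches to the exact linear-root limit
  $(F(1-\mu)-1)/(F-1-s_h)$, which is continuous with both regimes and
  reduces to the no-CI closed form as $s_h \to 0$. A fallback to the no-CI
  formula alone would be wrong in the $F\mu \to 1$ corner, which is why
  the linear form is used.
- The derivative is analytic for `sh = 0`
  ($F(1-\mu)/(1+p(F-1))^2$) and a central difference with step $10^{-7}$
  otherwise (clipped at the domain boundary). Derivative magnitudes within
  $10^{-9}$ of 1 are classified conservatively as unstable, so marginal
  cases never pass a "stable equilibrium exists" filter.
- `sh = 1` (complete CI) is rejected by validation — the explored regime
  is `sh` up to 0.45, and complete CI degenerates parts of the recursion —
  but `allow_complete_ci = TRUE` overrides for exploration.

## Batch protocol and summaries

`sim_protocol()` defaults encode the study conditions: `p0 = 0.4`, 10,000
generations, a 500-generation burn-in (discarding the transient spread
from `p0` to equilibrium), 25 replicates. Summaries use generations
`burn_in + 1` through `T` inclusive (9,500 values under defaults), with the
*sample* (n−1) standard deviation — at 9,500 points the difference from
the population SD is negligible but it is pinned for exactness.
Per-replicate seeds are drawn as a block from the base seed
(`sample.int` under `set.seed(base_seed)`), so replicates are individually
reproducible and the whole set replays bit-exactly from a manifest.

Parameter combinations whose deterministic prediction is loss (no interior
stable equilibrium) are flagged by `flag_predicted_loss()`, not removed:
downstream analyses choose. For fluctuating fitness the flag summarises
`F` by its median; since the geometric mean of a log-normal *is* the
median, the alternative reported rule uses the arithmetic mean
$E[F] = m\sqrt{CV^2+1}$. Replicates that are absorbed by drift despite a
predicted equilibrium are likewise retained, flagged `persisted = FALSE`,
and their post-loss zeros are included in `p_bar`/`p_sd` — the defensible
alternative (truncating at absorption) is computable from the trajectory
but is not the default.

Default grid axes in `param_grid()` span the plausible ranges above
(`mu` ∈ {0.001, 0.01, 0.05, 0.1, 0.2, 0.3}, `F` ∈ {1, 1.025, 1.05, 1.1,
1.2, 1.3, 1.5}, `sh` ∈ {0, 0.1, 0.45}, `N` ∈ {10³…10⁶}); they are fully
overridable, and any statistic aggregated *across* a grid (e.g. a median
`p_bar`) is necessarily grid-dependent.

## What the simulations emulate — and what they do not

The generator reproduces: drift of a cytoplasmic element under binomial
sampling at constant `N`; imperfect and heterogeneous maternal
transmission, including a low-transmitter subgroup (default 10% of
infected females at `mu = 0.8`, following field estimates from
*D. yakuba*-clade hosts); frequency-dependent CI advantage; and
generation-scale environmental fluctuation of fitness.

It does **not** model: varying or seasonally forced population size,
overlapping generations or age structure (male age strongly modulates CI
in real systems), unequal infection frequencies in the two sexes,
migration or spatial structure, density regulation, or selection on host
and symbiont genomes. Passing tests therefore establish internal
consistency of this model and its published closed forms — not that real
host populations behave this way; the largest fluctuations observed in
nature plausibly involve the mechanisms listed above that are out of
scope here.

## Validation strategy and problem sizes

The test suite validates the engine against independent routes rather than
against itself: per-ovum enumeration (`oracle_step_no_ci()`) versus the
engine's binomial draws by two-sample chi-square at `N = 200` with 10⁵
draws (α = 0.01); empirical one-step moments versus the closed forms
within 4 Monte-Carlo standard errors over a 27-point grid (states chosen
so trial counts are integral); the CI equilibrium against both a generic
polynomial root finder and fixed-point iteration of the map (1,000 random
parameter draws, agreement to 10⁻¹⁰); and the full batch protocol against
the analytic equilibria (25 replicates × 10,000 generations at `N = 10⁴`).
Directional parameter effects are checked on a reduced grid (`N = 10⁴`,
five `mu` × three `F` × three `sh` levels, 10 replicates each, loss-flagged
rows excluded) as signs of linear-effect fits plus pairwise monotonicity
in `mu`; sign checks rather than exhaustive pairwise ordering are used for
`F` and `sh` because at near-saturated equilibria the deterministic gaps
between adjacent `sh` levels approach the Monte-Carlo noise floor, and the
scientific claim under test is the direction of each effect. These sizes
were chosen as the smallest that leave Monte-Carlo error well inside each
tolerance.

## Known limitations

- The conditional-variance closed form is exact only at integral trial
  counts; elsewhere it carries an $O(1/N)$ rounding bias (invisible at the
  default `N` but measurable at `N` below ~10³).
- `equilibrium_ci()` reports both quadratic roots but the package does not
  analyse bistability in the $F\mu > 1$ regime.
- The stochastic engine treats `N` as the female effective population
  size; mapping it onto census sizes in any real system is the user's
  responsibility.
- With `fitness` medians very close to the invasion boundary and large
  `CV`, summaries mix quasi-stationary fluctuation with slow absorption;
  averaging over several base seeds (as the acceptance script does for the
  fluctuating-fitness regime) is advisable there.
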