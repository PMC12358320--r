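test_that("fitness draws honour the declared mode", {
  expect_identical(draw_fitness(fitness_spec(1.1), 5), rep(1.1, 5))

  set.seed(11)
  x <- draw_fitness(fitness_spec(1.05, cv = 0.1), 2e5)
  expect_equal(median(x), 1.05, tolerance = 0.002)
  expect_equal(sd(x) / mean(x), 0.1, tolerance = 0.01)
  # weakly fluctuating case: empirical percentiles near their closed forms
  set.seed(12)
  y <- draw_fitness(fitness_spec(1.05, cv = 0.01), 2e5)
  expect_equal(unname(quantile(y, c(0.025, 0.975))), c(1.03, 1.071),
               tolerance = 0.002)
})

test_that("stochastic steps absorb at zero and preserve degenerate states", {
  pars <- basic_params(N = 100, mu = 0.1, fitness = 1.1)
  absorbed <- step_no_ci(population_state(0, 100), pars, 1.1)
  expect_identical(absorbed$p, 0)
  expect_identical(absorbed$I, 0)

  # mu = 0, F = 1: S = I deterministically, p unchanged
  neutral <- basic_params(N = 100, mu = 0, fitness = 1)
  st <- step_no_ci(population_state(0.5, 100), neutral, 1)
  expect_identical(st$p, 0.5)
  expect_identical(st$I, 50)

  # fixation with perfect transmission under CI
  ci <- basic_params(N = 100, mu = 0, fitness = 1.1, sh = 0.45)
  fixed <- step_ci(population_state(1, 100), ci, 1.1)
  expect_identical(fixed$p, 1)
})

test_that("one-step empirical mean matches the conditional expectation", {
  pars <- basic_params(N = 1e4, mu = 0.05, fitness = 1.1)
  set.seed(21)
  mc <- moment_check(pars, p = 0.5, f_t = 1.1, n_draws = 1e5)
  # E[p'] = F (1 - mu) p / (p (F - 1) + 1) = 0.497619...
  expect_equal(mc$analytic_mean, 1.1 * 0.95 * 0.5 / 1.05, tolerance = 1e-12)
  expect_lt(abs(mc$z_mean), 3)
})

test_that("closed-form conditional moments match their derivation", {
  m <- conditional_moments(0.5, basic_params(N = 100, mu = 0.1, fitness = 1), 1)
  expect_equal(m$mean, 0.45)
  expect_equal(m$variance, 4.5e-4)
  expect_equal(conditional_moments(0, basic_params(), 1.1),
               tibble::tibble(mean = 0, variance = 0))
  # two-group variance is the sum of per-group binomial contributions
  pars <- lt_params(N = 1e4, mu = 0.001, fitness = 1.1)
  m2 <- conditional_moments(0.5, pars, 1.1)
  g <- pars$transmission$groups
  by_hand <- 0.5 * sum(1.1 * g$fraction * g$mu * (1 - g$mu)) / (1e4 * 1.05^2)
  expect_equal(m2$variance, by_hand)
  expect_error(conditional_moments(0.5, basic_params(sh = 0.1), 1.1), "sh = 0")
})

test_that("the CI step reduces to the no-CI step when sh = 0", {
  pars <- basic_params(N = 500, mu = 0.1, fitness = 1.1, sh = 0)
  for (p in c(0.2, 0.5, 0.9)) {
    st <- population_state(p, 500)
    set.seed(31)
    a <- step_ci(st, pars, 1.1)
    set.seed(31)
    b <- step_no_ci(st, pars, 1.1)
    expect_identical(a, b)
  }
})

test_that("large populations recover the deterministic projection", {
  pars <- basic_params(N = 1e7, mu = 0.001, fitness = 1.1)
  target <- project_frequency(0.4, 1.1, 0.001, 0)
  set.seed(41)
  draws <- symdrift:::sample_offspring_frequency(0.4, 4e6, pars, 1.1, n = 200)
  expect_true(all(abs(draws - target) < 1e-3))

  ci <- basic_params(N = 1e7, mu = 0.05, fitness = 1.05, sh = 0.45)
  target_ci <- project_frequency(0.5, 1.05, 0.05, 0.45)
  set.seed(42)
  draws_ci <- symdrift:::sample_offspring_frequency(0.5, 5e6, ci, 1.05, n = 200)
  expect_true(all(abs(draws_ci - target_ci) < 1e-3))
})

test_that("identical subgroups are distributionally equivalent to one group", {
  one <- basic_params(N = 1e4, mu = 0.1, fitness = 1.1)
  three <- model_params(
    N = 1e4,
    transmission = transmission_profile(mu = rep(0.1, 3),
                                        fraction = rep(1 / 3, 3)),
    fitness = fitness_spec(1.1)
  )
  set.seed(51)
  a <- symdrift:::sample_offspring_frequency(0.6, 6000, one, 1.1, n = 1e5)
  b <- symdrift:::sample_offspring_frequency(0.6, 6000, three, 1.1, n = 1e5)
  se_diff <- sqrt(sd(a)^2 / 1e5 + sd(b)^2 / 1e5)
  expect_lt(abs(mean(a) - mean(b)), 4 * se_diff)
  expect_lt(abs(sd(a)^2 / sd(b)^2 - 1), 0.05)
})

test_that("trajectories are reproducible and absorb permanently", {
  pars <- basic_params(N = 1e3, mu = 0.001, fitness = 1.1)
  prot <- sim_protocol(generations = 500, burn_in = 100, n_reps = 1)
  t1 <- simulate_trajectory(pars, prot, seed = 99)
  t2 <- simulate_trajectory(pars, prot, seed = 99)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_true(all(t1$p >= 0 & t1$p <= 1))
  expect_equal(t1$I, round(1e3 * t1$p))

  # p0 = 0: all-zero trajectory absorbed at generation 0
  z <- simulate_trajectory(pars, sim_protocol(p0 = 0, generations = 100, burn_in = 10))
  expect_true(all(z$p == 0))
  expect_identical(attr(z, "absorbed_at"), 0L)

  # once zero, zero thereafter
  lossy <- basic_params(N = 200, mu = 0.3, fitness = 1.05)
  tr <- simulate_trajectory(lossy, sim_protocol(generations = 3000, burn_in = 100), seed = 5)
  ab <- attr(tr, "absorbed_at")
  expect_false(is.na(ab))
  expect_true(all(tr$p[tr$generation >= ab] == 0))
})

test_that("a long run at large N settles at the analytic equilibrium", {
  pars <- basic_params(N = 1e6, mu = 0.001, fitness = 1.1)
  tr <- simulate_trajectory(pars, sim_protocol(generations = 2000, burn_in = 100), seed = 8)
  expect_lt(abs(tr$p[2001] - 0.989), 0.01)
})

test_that("adult resampling adds Wright-Fisher sampling noise", {
  pars <- basic_params(N = 500, mu = 0, fitness = 1)
  prot <- sim_protocol(generations = 200, burn_in = 50)
  # without resampling, mu = 0 and F = 1 is fully deterministic
  frozen <- simulate_trajectory(pars, prot, seed = 3)
  expect_true(all(frozen$p == 0.4))
  wf <- simulate_trajectory(pars, prot, seed = 3, adult_resampling = TRUE)
  expect_gt(sd(wf$p), 0)
})
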