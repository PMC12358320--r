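test_that("per-ovum oracle equals the engine draw in distribution", {
  pars <- basic_params(N = 200, mu = 0.1, fitness = 1)
  n <- 3e4
  set.seed(61)
  engine_p <- symdrift:::sample_offspring_frequency(0.5, 100, pars, 1, n = n)
  oracle_p <- vapply(seq_len(n), function(i) {
    oracle_step_no_ci(0.5, 100, pars, 1)
  }, numeric(1))
  # F = 1: counts recover as S = p' * N
  engine_s <- round(engine_p * 200)
  oracle_s <- round(oracle_p * 200)
  expect_gt(two_sample_chisq_p(engine_s, oracle_s), 0.01)
})

test_that("oracle degenerate cases are exact", {
  perfect <- basic_params(N = 100, mu = 0, fitness = 1)
  # mu = 0: every ovum infected, S equals total ova in both engine and oracle
  expect_identical(oracle_step_no_ci(0.5, 50, perfect, 1), 0.5)
  st <- step_no_ci(population_state(0.5, 100), perfect, 1)
  expect_identical(st$p, 0.5)

  # a single infected female with F = 1, mu = 0.5: S ~ Bernoulli(0.5)
  single <- basic_params(N = 100, mu = 0.5, fitness = 1)
  set.seed(62)
  s_draws <- vapply(1:4000, function(i) {
    oracle_step_no_ci(0.01, 1, single, 1) * 100 / 1  # back out S
  }, numeric(1))
  expect_true(all(s_draws %in% c(0, 1)))
  expect_equal(mean(s_draws), 0.5, tolerance = 0.03)
})

test_that("oracle CI step matches the engine under deterministic thinning", {
  pars <- basic_params(N = 400, mu = 0.1, fitness = 1, sh = 0.45)
  n <- 3e4
  set.seed(63)
  engine_p <- symdrift:::sample_offspring_frequency(0.5, 200, pars, 1, n = n)
  oracle_p <- vapply(seq_len(n), function(i) {
    oracle_step_ci(0.5, 200, pars, 1)
  }, numeric(1))
  se <- sqrt(sd(engine_p)^2 / n + sd(oracle_p)^2 / n)
  expect_lt(abs(mean(engine_p) - mean(oracle_p)), 4 * se)
  expect_lt(abs(sd(engine_p)^2 / sd(oracle_p)^2 - 1), 0.1)

  # Bernoulli CI survival is a distinct (noisier) sensitivity variant
  set.seed(64)
  bern_p <- vapply(seq_len(n), function(i) {
    oracle_step_ci(0.5, 200, pars, 1, ci_bernoulli = TRUE)
  }, numeric(1))
  expect_gt(sd(bern_p), 0)
})

test_that("moment reports flag nothing on-model and degenerate cases are exact", {
  set.seed(65)
  mc <- moment_check(basic_params(N = 1e4, mu = 0.1, fitness = 1.1),
                     p = 0.5, f_t = 1.1, n_draws = 5e4)
  expect_lt(abs(mc$z_mean), 4)
  expect_lt(abs(mc$z_var), 4)

  # p = 0: every draw zero
  mc0 <- moment_check(basic_params(), p = 0, f_t = 1.1, n_draws = 100)
  expect_equal(mc0$empirical_mean, 0)
  expect_equal(mc0$empirical_var, 0)

  # sh = 0.45, mu = 0, p = 1: no uninfected ova anywhere, zero variance
  set.seed(66)
  mc1 <- moment_check(basic_params(N = 1000, mu = 0, fitness = 1.1, sh = 0.45),
                      p = 1, f_t = 1.1, n_draws = 1000)
  expect_equal(mc1$empirical_var, 0)
  expect_equal(mc1$empirical_mean, 1)
})

test_that("absorption profiles separate sub- and super-critical regimes", {
  prot <- sim_protocol(generations = 10000, base_seed = 13)
  # deterministically lost: every small-N run absorbs well before the end
  lost <- absorption_profile(basic_params(N = 1e3, mu = 0.05, fitness = 1.05),
                             prot, n_runs = 20)
  expect_true(all(lost$absorbed))
  expect_true(all(lost$absorbed_at < 10000))

  # strongly held equilibrium at large N: no absorption at all
  held <- absorption_profile(
    basic_params(N = 1e5, mu = 0.001, fitness = 1.3, sh = 0.45),
    sim_protocol(generations = 2000, burn_in = 100, base_seed = 14), n_runs = 10
  )
  expect_false(any(held$absorbed))

  # p0 = 0 absorbs at generation zero
  z <- absorption_profile(basic_params(N = 1e3),
                          sim_protocol(p0 = 0, generations = 10, burn_in = 0, base_seed = 2),
                          n_runs = 3)
  expect_true(all(z$absorbed_at == 0))
})
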