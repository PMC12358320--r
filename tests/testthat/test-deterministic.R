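test_that("the one-generation projection matches direct evaluation", {
  # absorbing boundary and fixation with perfect transmission
  expect_identical(project_frequency(0, 1.3, 0.1, 0.45), 0)
  expect_equal(project_frequency(1, 1.1, 0, 0), 1)
  # direct evaluation: 0.4 * 1.1 * 0.999 / (1 + 0.4 * 0.1)
  expect_equal(project_frequency(0.4, 1.1, 0.001, 0), 0.42265384615384621,
               tolerance = 1e-15)
})

test_that("invasion requires F(1 - mu) strictly above one", {
  expect_true(invasion_condition(1.1, 0.001))
  expect_false(invasion_condition(1.0, 0.0))  # boundary is strict
  expect_true(invasion_condition(1.1, 0.0809))
  expect_false(invasion_condition(1.05, 0.05))
})

test_that("no-CI equilibrium matches the closed form", {
  eq <- equilibrium_no_ci(1.1, 0.001)
  expect_equal(eq$p_hat, 1 - 0.001 * 1.1 / 0.1)
  expect_equal(round(eq$p_hat, 3), 0.989)
  expect_identical(eq$stability, "stable")

  lt <- equilibrium_no_ci(1.1, 0.0809)
  expect_equal(lt$p_hat, 0.1101, tolerance = 1e-10)
  expect_identical(lt$stability, "stable")

  # boundary F = 1/(1 - mu): equilibrium collapses to 0
  mu <- 0.05
  eq0 <- equilibrium_no_ci(1 / (1 - mu), mu)
  expect_equal(eq0$p_hat, 0)

  # sub-critical: no interior equilibrium
  none <- equilibrium_no_ci(1.05, 0.05)
  expect_identical(none$stability, "none")
  expect_true(is.na(none$p_hat))
})

test_that("CI equilibrium is a verified stable fixed point", {
  # perfect transmission: discriminant collapses and the stable root is 1
  eq1 <- equilibrium_ci(1.1, 0, 0.45)
  expect_equal(eq1$p_hat, 1, tolerance = 1e-12)

  # continuity with the no-CI closed form as sh -> 0
  expect_equal(equilibrium_ci(1.1, 0.001, 1e-8)$p_hat,
               equilibrium_no_ci(1.1, 0.001)$p_hat, tolerance = 1e-5)

  # agreement with the fixed point located by iterating the map from 0.5
  eq <- equilibrium_ci(1.05, 0.05, 0.45)
  p_star <- iterate_to_fixed_point(1.05, 0.05, 0.45)
  expect_equal(eq$p_hat, p_star, tolerance = 1e-10)
})

test_that("CI equilibria agree with a generic polynomial root finder", {
  set.seed(42)
  for (i in 1:200) {
    f <- runif(1, 1.01, 1.5)
    mu <- runif(1, 0, 0.95 * (1 - 1 / f))
    sh <- runif(1, 0.01, 0.45)
    eq <- equilibrium_ci(f, mu, sh)
    a <- sh * (1 - f * mu)
    b <- f - 1 - sh
    cc <- 1 - f * (1 - mu)
    roots <- polyroot(c(cc, b, a))
    real_roots <- Re(roots)[abs(Im(roots)) < 1e-9]
    in_unit <- real_roots[real_roots >= 0 & real_roots <= 1]
    expect_equal(eq$p_hat, max(in_unit), tolerance = 1e-9)
  }
})

test_that("reported equilibria satisfy fixed-point consistency", {
  for (mu in c(0, 0.001, 0.05, 0.1, 0.2, 0.3)) {
    for (f in c(1.025, 1.05, 1.1, 1.3, 1.5)) {
      for (sh in c(0, 0.1, 0.45)) {
        eq <- if (sh == 0) equilibrium_no_ci(f, mu) else equilibrium_ci(f, mu, sh)
        if (is.finite(eq$p_hat)) {
          expect_lt(abs(project_frequency(eq$p_hat, f, mu, sh) - eq$p_hat),
                    1e-12)
        }
      }
    }
  }
})

test_that("equilibrium frequency is monotone in mu, fitness and CI strength", {
  set.seed(7)
  p_hat_of <- function(f, mu, sh) {
    if (sh == 0) equilibrium_no_ci(f, mu)$p_hat else equilibrium_ci(f, mu, sh)$p_hat
  }
  for (i in 1:200) {
    f <- runif(1, 1.05, 1.5)
    sh <- sample(c(0, runif(1, 0.01, 0.45)), 1)
    mus <- sort(runif(2, 0, 0.9 * (1 - 1 / f)))
    expect_gte(p_hat_of(f, mus[1], sh), p_hat_of(f, mus[2], sh))

    mu <- runif(1, 0, 0.1)
    fs <- sort(runif(2, 1 / (1 - mu) + 0.01, 1.5))
    expect_lte(p_hat_of(fs[1], mu, sh), p_hat_of(fs[2], mu, sh) + 1e-12)

    shs <- sort(runif(2, 0.005, 0.45))
    expect_lte(p_hat_of(fs[1], mu, shs[1]), p_hat_of(fs[1], mu, shs[2]) + 1e-12)
  }
})

test_that("stability is classified by the map derivative", {
  expect_identical(classify_stability(0, 1.1, 0.001), "unstable")
  eq <- equilibrium_no_ci(1.1, 0.001)
  expect_identical(classify_stability(eq$p_hat, 1.1, 0.001), "stable")
  # sub-critical infection: loss is stable
  expect_identical(classify_stability(0, 1.05, 0.05), "stable")
  expect_error(classify_stability(0.5, 1.1, 0.001), "not a fixed point")
})

test_that("deterministic iteration converges to the stable equilibrium", {
  traj <- iterate_deterministic(0.4, 1.1, 0.001, generations = 10000)
  expect_equal(nrow(traj), 10001)
  expect_lt(abs(traj$p[10001] - 0.989), 1e-8)

  lost <- iterate_deterministic(0.4, 1.05, 0.05, generations = 10000)
  expect_lt(lost$p[10001], 1e-6)

  zero <- iterate_deterministic(0, 1.1, 0.001, generations = 100)
  expect_true(all(zero$p == 0))
})

test_that("equilibrium tidiers expose roots and a one-row summary", {
  eq <- equilibrium_ci(1.05, 0.05, 0.45)
  td <- tidy(eq)
  expect_equal(nrow(td), 2)
  gl <- glance(eq)
  expect_equal(gl$p_hat, eq$p_hat)
  expect_identical(gl$stability, "stable")
})
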