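test_that("implied population moments follow the common-factor structure", {
  # zero loadings: Sigma = Theta, mu = nu
  items <- toy_items(4)
  m0 <- population_model(matrix(0, 4, 1), matrix(1), rep(2, 4),
                         intercepts = 1:4, item_ids = items)
  mom0 <- implied_population_moments(m0)
  expect_equal(unname(mom0$Sigma), diag(2, 4))
  expect_equal(unname(mom0$mu), as.numeric(1:4))

  # equal-loading one-factor: off-diagonals lambda^2
  m1 <- one_factor_population(lambda = 0.6, k = 5)
  mom1 <- implied_population_moments(m1)
  expect_equal(unname(diag(mom1$Sigma)), rep(1, 5))
  expect_equal(unname(mom1$Sigma[1, 2]), 0.36)

  # bifactor example against element-by-element assembly
  bp <- bifactor_population(k = 8, group_items = 5:8, general = 0.7,
                            group = 0.5, items = toy_items(8))
  mom <- implied_population_moments(bp)
  L <- bp$loadings
  manual <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    manual[i, j] <- sum(L[i, ] * L[j, ]) + (i == j) * bp$residual_cov[i, i]
  }
  expect_equal(unname(mom$Sigma), manual)

  # invalid inputs rejected
  expect_error(population_model(matrix(1, 2, 1), matrix(-1), rep(1, 2)),
               "positive")
})

test_that("simulation is seed-reproducible and converges to implied moments", {
  pop <- phq9_population()
  a <- simulate_responses(pop, 200, seed = 99)
  b <- simulate_responses(pop, 200, seed = 99)
  expect_identical(a$values, b$values)

  big <- simulate_responses(pop, 1e5, seed = 3, discretize = FALSE)
  mom <- implied_population_moments(pop)
  expect_lt(max(abs(stats::cov(big$values) - mom$Sigma)), 0.02)
  expect_lt(max(abs(colMeans(big$values) - mom$mu)), 0.02)
})

test_that("MCAR missingness lands at the nominal rate", {
  pop <- one_factor_population(k = 5)
  pop$missing_rate <- 0.05
  dat <- simulate_responses(pop, 10000, seed = 8)
  prop <- mean(is.na(dat$values))
  se <- sqrt(0.05 * 0.95 / (10000 * 5))
  expect_lt(abs(prop - 0.05), 3 * se)
})

test_that("discretization counts thresholds below the value and is monotone", {
  expect_equal(discretize(-5, c(-1, 0, 1)), 0)
  expect_equal(discretize(0.5, c(-1, 0, 1)), 2)
  expect_equal(discretize(c(-2, -0.5, 0.5, 2), c(-1, 0, 1)), c(0, 1, 2, 3))
  expect_error(discretize(0, c(1, 1, 2)), "increasing")

  set.seed(12)
  x <- sort(rnorm(500))
  codes <- discretize(x, c(-0.8, 0.1, 0.9))
  expect_true(all(diff(codes) >= 0))

  # standard-normal category proportions via the normal CDF
  set.seed(13)
  z <- rnorm(2e5)
  prop <- tabulate(discretize(z, c(-1, 0, 1)) + 1L, 4L) / 2e5
  expect_equal(prop, c(pnorm(-1), 0.5 - pnorm(-1), 0.5 - pnorm(-1),
                       pnorm(-1)), tolerance = 0.01)
})

test_that("invariance scenarios plant exactly the declared differences", {
  base <- phq9_population()
  sc0 <- make_invariance_scenario(base, list(), c("A", "B"), c(100, 100))
  expect_equal(nrow(sc0$manifest), 0L)
  expect_identical(sc0$groups$A$model$intercepts,
                   sc0$groups$B$model$intercepts)

  sc1 <- make_invariance_scenario(
    base, list(violation_spec("intercept", "phq2", 0.3, "B")),
    c("A", "B"), c(100, 100))
  expect_equal(sc1$manifest$parameter, "nu[phq2]")
  mA <- implied_population_moments(sc1$groups$A$model)
  mB <- implied_population_moments(sc1$groups$B$model)
  expect_equal(unname(mB$mu - mA$mu),
               as.numeric(0.3 * (phq9_scale()$items == "phq2")))
  expect_equal(mA$Sigma, mB$Sigma)

  sc2 <- make_invariance_scenario(
    base, list(violation_spec("residual_variance", "phq5", 2, "B",
                              multiplicative = TRUE)),
    c("A", "B"), c(100, 100))
  expect_equal(sc2$manifest$parameter, "theta[phq5]")
  dS <- implied_population_moments(sc2$groups$B$model)$Sigma -
    implied_population_moments(sc2$groups$A$model)$Sigma
  expect_equal(sum(abs(dS) > 1e-12), 1L)   # only theta_5 moved
  expect_gt(dS["phq5", "phq5"], 0)

  expect_error(make_invariance_scenario(
    base, list(violation_spec("residual_variance", "phq5", -5, "B")),
    c("A", "B"), c(100, 100)))
})

test_that("scenario simulation derives deterministic child seeds per group", {
  sc <- two_group_scenario(n = 50)
  d1 <- simulate_scenario(sc, seed = 21)
  d2 <- simulate_scenario(sc, seed = 21)
  expect_identical(d1$values, d2$values)
  expect_equal(unique(d1$grouping$group), c("A", "B"))
  d3 <- simulate_scenario(sc, seed = 22)
  expect_false(identical(d1$values, d3$values))
})

test_that("default thresholds produce right-skewed Likert marginals", {
  pop <- phq9_population()
  dat <- simulate_responses(pop, 20000, seed = 31)
  prop0 <- mean(dat$values == 0)
  expect_gt(prop0, 0.5)      # most endorse the lowest category
  means <- colMeans(dat$values)
  expect_true(all(means < 1.0))  # low item means, as in severity screening
})
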