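test_that("MM-regression matches least squares on clean normal data", {
  set.seed(191)
  n <- 2000
  x <- rnorm(n)
  y <- 1 + 0.8 * x + rnorm(n)
  X <- cbind(1, x)
  mm <- mm_regression(y, X)
  ols <- coef(lm(y ~ x))
  expect_lt(max(abs(mm$coefficients - ols) / pmax(abs(ols), 0.1)), 0.02)
  expect_true(mm$converged)
  expect_error(mm_regression(y, cbind(1, x, x)), "collinear")
})

test_that("MM-regression resists gross outliers where least squares fails", {
  set.seed(193)
  wins <- 0
  B <- 100
  for (b in seq_len(B)) {
    n <- 300
    x <- rnorm(n)
    y <- 2 + 1 * x + rnorm(n)
    out <- sample(n, 30)            # 10% gross bad-leverage outliers
    x[out] <- x[out] + 6
    y[out] <- y[out] - 15
    mm <- mm_regression(y, cbind(1, x))$coefficients[2]
    ls <- coef(lm(y ~ x))[2]
    if (abs(mm - 1) < abs(ls - 1)) wins <- wins + 1
  }
  expect_gte(wins / B, 0.95)
})

test_that("intercept-only MM fit lands near the median on symmetric data", {
  set.seed(197)
  y <- rt(800, df = 3)
  mm <- mm_regression(y, matrix(1, 800, 1))
  expect_lt(abs(mm$coefficients[1] - median(y)), 0.1)
})

test_that("observed SES has the stated sign convention and scale", {
  set.seed(199)
  n <- 4000
  g <- rep(c("base", "up"), each = n / 2)
  y <- rnorm(n)
  # identical groups: SES ~ 0
  s0 <- observed_ses(y, g)
  expect_lt(abs(s0$ses[2]), 0.08)
  # planted shift of one residual-scale unit: SES ~ 1
  y1 <- y + (g == "up") * 1.0
  s1 <- observed_ses(y1, g)
  expect_equal(s1$ses[2], 1, tolerance = 0.08)
  # contrast below baseline: negative SES
  y2 <- y - (g == "up") * 0.5
  expect_lt(observed_ses(y2, g)$ses[2], 0)
  # descriptives reproduce direct computation
  expect_equal(s1$mean[s1$subgroup == "up"], mean(y1[g == "up"]))
  expect_equal(s1$sd[s1$subgroup == "base"], sd(y1[g == "base"]))
  expect_warning(observed_ses(rnorm(15), rep(c("a", "b"), c(9, 6))),
                 "n < 10")
})

test_that("latent SES recovers a planted latent shift", {
  items <- toy_items(6)
  L <- matrix(0.7, 6, 1, dimnames = list(items, "f"))
  base <- population_model(L, matrix(1), rep(1 - 0.49, 6),
                           item_ids = items, factor_ids = "f")
  base$thresholds <- default_thresholds(base)
  shifted <- base
  shifted$latent_means <- 0.3
  scen <- list(groups = list(A = list(model = base, n = 1500),
                             B = list(model = shifted, n = 1500)),
               manifest = NULL)
  dat <- simulate_scenario(scen, seed = 211, discretize = FALSE)
  spec <- cfa_model(items, list(f = items))
  lat <- latent_ses(dat, spec, "group")
  expect_lt(abs(lat$ses[2] - 0.3), 0.08)
  expect_lt(lat$p[2], 0.01)
  # no shift: SES ~ 0
  scen0 <- list(groups = list(A = list(model = base, n = 1500),
                              B = list(model = base, n = 1500)),
                manifest = NULL)
  dat0 <- simulate_scenario(scen0, seed = 212, discretize = FALSE)
  lat0 <- latent_ses(dat0, spec, "group")
  expect_lt(abs(lat0$ses[2]), 0.1)
})

test_that("latent SES refuses groupings without scalar invariance", {
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  fake_ladder <- structure(list(attained = "metric", records = list()),
                           class = "ladder_result")
  dat <- simulate_scenario(two_group_scenario(n = 200), seed = 213)
  expect_error(latent_ses(dat, spec, "group", ladder = fake_ladder),
               "scalar invariance not attained")
})

test_that("effect comparison reports both variants per contrast", {
  items <- toy_items(6)
  L <- matrix(0.65, 6, 1, dimnames = list(items, "f"))
  base <- population_model(L, matrix(1), rep(1 - 0.65^2, 6),
                           item_ids = items, factor_ids = "f")
  base$thresholds <- default_thresholds(base)
  shifted <- base
  shifted$latent_means <- 0.35
  scen <- list(groups = list(A = list(model = base, n = 1200),
                             B = list(model = shifted, n = 1200)),
               manifest = NULL)
  dat <- simulate_scenario(scen, seed = 223)
  sdef <- scale_definition("TOY", items,
                           list(a = items[1:3], b = items[4:6]))
  ef <- effect_comparison(dat, sdef, "group")
  expect_equal(nrow(ef), 2L)
  expect_true(is.na(ef$observed_ses[1]))       # baseline row
  expect_gt(ef$observed_ses[2], 0)
  expect_gt(ef$latent_ses[2], 0)
  # attenuation: latent effect at least as large as the unit-weighted one
  expect_gte(abs(ef$latent_ses[2]), abs(ef$observed_ses[2]))
})
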