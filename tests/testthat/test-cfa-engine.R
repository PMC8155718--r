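test_that("model catalog wires subscales and reproduces analytic dfs", {
  cat9 <- model_catalog(phq9_scale())
  expect_named(cat9, c("one_factor", "two_factor_correlated",
                       "one_factor_correlated_residuals",
                       "bifactor_s_minus_1"))
  # somatic factor on exactly items 3, 4, 5
  pt <- cat9$two_factor_correlated$ptable
  som_rows <- pt[pt$mat == "lambda" & pt$col == 2, "row"]
  expect_equal(phq9_scale()$items[som_rows], paste0("phq", 3:5))
  expect_equal(cfa_df(cat9$one_factor), 27L)
  expect_equal(cfa_df(cat9$two_factor_correlated), 26L)
  expect_equal(cfa_df(cat9$bifactor_s_minus_1), 21L)
  cat7 <- model_catalog(gad7_scale())
  expect_equal(cfa_df(cat7$one_factor), 14L)
  # correlated-residual pairs: all within-somatic pairs
  ptc <- cat7$one_factor_correlated_residuals$ptable
  expect_equal(sum(ptc$mat == "theta" & ptc$row != ptc$col), 3L)

  bad <- scale_definition("B", paste0("x", 1:4),
                          list(cognitive = paste0("x", 1:3),
                               somatic = "x4"))
  expect_error(model_catalog(bad), ">= 2 items")
})

test_that("ml_discrepancy matches its closed form and brute force", {
  # p = 1 closed form
  expect_equal(ml_discrepancy(matrix(2), 0, matrix(1), 0),
               1 - log(2) + (0 - 0), tolerance = 1e-12)
  # zero at equality
  S <- random_spd(4, 1)
  expect_equal(ml_discrepancy(S, 1:4, S, 1:4), 0, tolerance = 1e-10)
  # random instances against an independent evaluation
  for (k in 1:40) {
    p <- sample(2:5, 1)
    S <- random_spd(p, 100 + k)
    Sig <- random_spd(p, 200 + k)
    yb <- rnorm(p)
    mu <- rnorm(p)
    expect_equal(ml_discrepancy(S, yb, Sig, mu),
                 as.numeric(brute_force_fml(S, yb, Sig, mu)),
                 tolerance = 1e-8)
  }
  expect_error(ml_discrepancy(diag(c(1, -1)), c(0, 0), diag(2), c(0, 0)),
               "positive definite")
})

test_that("implied_moments matches brute-force matrix assembly", {
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  comp <- psyvalid:::compile_spec(spec)
  set.seed(5)
  for (k in 1:20) {
    th <- runif(comp$q, 0.2, 0.9)
    mom <- implied_moments(spec, th)
    mm <- psyvalid:::fill_group(comp$groups[[1]], th)
    expect_equal(unname(mom$Sigma),
                 unname(mm$Lam %*% mm$Psi %*% t(mm$Lam) + mm$Th))
    expect_equal(unname(mom$mu),
                 unname(mm$nu + drop(mm$Lam %*% mm$al)))
  }
  expect_error(implied_moments(spec, 1:3), "length")
})

test_that("fitting exact population moments recovers the generator", {
  pop <- phq9_population()
  mom <- implied_population_moments(pop)
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  fit <- fit_cfa(list(S = mom$Sigma, ybar = mom$mu, n = 5000), spec)
  expect_lt(fit$F, 1e-8)
  expect_equal(unname(fit$theta["psi.cognitive.somatic"]), 0.77,
               tolerance = 1e-4)
  lam_hat <- fit$groups[[1]]$Lambda
  expect_equal(unname(lam_hat[lam_hat != 0]),
               unname(pop$loadings[pop$loadings != 0]), tolerance = 1e-4)
})

test_that("casewise parameter recovery at n = 5000 stays within 3 MC SEs", {
  pop <- phq9_population()
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  dat <- simulate_responses(pop, 5000, seed = 17, discretize = FALSE)
  fit <- fit_cfa(dat, spec)
  se <- sqrt(diag(naive_vcov(fit)))
  for (fac in colnames(pop$loadings)) {
    loaded <- rownames(pop$loadings)[pop$loadings[, fac] != 0]
    for (it in loaded) {
      par <- sprintf("lam.%s.%s", it, fac)
      expect_lt(abs(fit$theta[par] - pop$loadings[it, fac]),
                3 * se[par] + 1e-8)
    }
  }
  expect_lt(abs(fit$theta["psi.cognitive.somatic"] - 0.77),
            3 * se["psi.cognitive.somatic"])
})

test_that("saturated model reproduces any input exactly with df 0", {
  items <- toy_items(3)
  spec <- saturated_spec(items)
  expect_equal(cfa_df(spec), 0L)
  S <- random_spd(3, 9)
  fit <- fit_cfa(list(S = S, ybar = c(1, 2, 3), n = 500), spec)
  expect_lt(fit$T_ML, 1e-5)
  expect_lt(max(abs(fit$groups[[1]]$Sigma - S)), 1e-4)
})

test_that("marker-item and unit-variance identifications are equivalent", {
  pop <- phq9_population()
  dat <- simulate_responses(pop, 800, seed = 23)
  sdef <- phq9_scale()
  f_unit <- fit_cfa(dat, cfa_model(sdef$items, sdef$subscales,
                                   identification = "unit_factor_variance"))
  f_mark <- fit_cfa(dat, cfa_model(sdef$items, sdef$subscales,
                                   identification = "marker_item"))
  expect_equal(f_unit$T_ML, f_mark$T_ML, tolerance = 1e-5)
  expect_equal(f_unit$df, f_mark$df)
  expect_equal(standardized_solution(f_unit)$loadings,
               standardized_solution(f_mark)$loadings, tolerance = 1e-5)
})

test_that("nesting monotonicity holds across the model catalog", {
  pop <- phq9_population()
  dat <- simulate_responses(pop, 700, seed = 29)
  fits <- lapply(model_catalog(phq9_scale()), function(sp)
    fit_cfa(dat, sp))
  # the one-factor model is nested in each alternative
  for (alt in c("two_factor_correlated", "one_factor_correlated_residuals",
                "bifactor_s_minus_1")) {
    expect_gte(fits$one_factor$T_ML, fits[[alt]]$T_ML - 1e-6)
  }
})

test_that("sandwich and naive covariances agree under normality and diverge
           with kurtosis", {
  pop <- phq9_population()
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  datn <- simulate_responses(pop, 20000, seed = 37, discretize = FALSE)
  fitn <- fit_cfa(datn, spec)
  Vr <- sandwich_vcov(fitn)
  Vn <- naive_vcov(fitn)
  expect_equal(Vr, t(Vr))
  expect_true(all(diag(Vr) >= 0))
  ratio <- sqrt(diag(Vr) / diag(Vn))
  expect_true(all(abs(ratio - 1) < 0.05))

  datd <- simulate_responses(pop, 5000, seed = 38)
  fitd <- fit_cfa(datd, spec)
  rd <- sqrt(diag(sandwich_vcov(fitd)) / diag(naive_vcov(fitd)))
  var_pars <- grepl("^th\\.", names(fitd$theta))
  expect_gt(mean(rd[var_pars]), 1)
})

test_that("scaling factor is near 1 for normal data and positive always", {
  pop <- phq9_population()
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  datn <- simulate_responses(pop, 20000, seed = 41, discretize = FALSE)
  scn <- scaled_statistic(fit_cfa(datn, spec))
  expect_lt(abs(scn$c_hat - 1), 0.05)
  datd <- simulate_responses(pop, 1500, seed = 43)
  scd <- scaled_statistic(fit_cfa(datd, spec))
  expect_gt(scd$c_hat, 0)
})

test_that("scaled chi-square difference reduces to the plain difference", {
  pop <- phq9_population()
  dat <- simulate_responses(pop, 600, seed = 47)
  cat9 <- model_catalog(phq9_scale())
  f1 <- fit_cfa(dat, cat9$one_factor)
  f2 <- fit_cfa(dat, cat9$two_factor_correlated)
  d <- scaled_chisq_difference(f1, f2)
  expect_equal(d$delta_df, 1L)
  expect_equal(d$delta_T * d$c_d, f1$T_ML - f2$T_ML, tolerance = 1e-8)
  # identical models: zero difference
  d0 <- scaled_chisq_difference(f1, f1)
  expect_equal(d0$delta_T, 0)
  expect_equal(d0$p, 1)
  expect_error(scaled_chisq_difference(f2, f1), "degrees of freedom")
})

test_that("standardized solution matches a refit on the correlation scale", {
  pop <- phq9_population()
  dat <- simulate_responses(pop, 1200, seed = 53)
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  fit <- fit_cfa(dat, spec)
  std <- standardized_solution(fit)
  # oracle: refit after rescaling the sample moments to correlations
  S <- fit$data[[1]]$S
  d <- 1 / sqrt(diag(S))
  R <- S * tcrossprod(d)
  refit <- fit_cfa(list(S = R, ybar = rep(0, 9), n = fit$n[[1]]), spec)
  lam_refit <- refit$groups[[1]]$Lambda
  expect_equal(std$loadings, lam_refit, tolerance = 1e-3)
  # single-item identity: residual proportion = 1 - lambda^2
  expect_equal(unname(diag(std$residual_cor)),
               unname(1 - rowSums(std$loadings^2) -
                        2 * std$loadings[, 1] * std$loadings[, 2] *
                        std$factor_cor[1, 2]),
               tolerance = 1e-6)
})

test_that("degenerate and invalid fits raise informative errors", {
  items <- toy_items(4)
  expect_error(cfa_model(items, list(f = "i1")), "fewer than 2")
  expect_error(cfa_model(items, list(f = c("i1", "zz"))), "unknown item")
  pop <- one_factor_population(k = 4)
  dat <- simulate_responses(pop, 200, seed = 3)
  dat$values[1, 2] <- NA
  expect_error(fit_cfa(dat, cfa_model(items, list(f = items))),
               "complete_cases")
})
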