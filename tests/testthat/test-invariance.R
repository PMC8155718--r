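test_that("constraint levels reproduce the published df arithmetic", {
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  dfs <- vapply(c("configural", "metric", "scalar", "factor_variance",
                  "residual"), function(lv)
    cfa_df(constrain_invariance(spec, c("g1", "g2"), lv)), integer(1))
  expect_equal(unname(dfs), c(52L, 59L, 66L, 68L, 75L))
  # freeing 3 residuals removes exactly 3 constraints
  part <- constrain_invariance(spec, c("g1", "g2"), "residual",
                               freed = list(residual = paste0("phq",
                                                              c(2, 6, 7))))
  expect_equal(cfa_df(part), 72L)
  # three-group configural for the same model
  expect_equal(cfa_df(constrain_invariance(spec, paste0("t", 0:2),
                                           "configural")), 78L)
  # freeing at a level above the requested one is rejected
  expect_error(constrain_invariance(spec, c("a", "b"), "metric",
                                    freed = list(scalar = "phq1")),
               "cannot free")
})

test_that("decision rule reproduces published pass/fail patterns", {
  # clearly degraded fit: fail
  expect_false(invariance_decision(-0.054, 0.018, 0.0001))
  # negligible change: pass
  expect_true(invariance_decision(-0.007, 0.001, 0.081))
  expect_true(invariance_decision(0, 0, 1))
  # index rule alone can pass despite significant chi-square
  expect_true(invariance_decision(-0.005, 0.002, 0.001))
  # non-significant test alone can pass despite index degradation
  expect_true(invariance_decision(-0.05, 0.02, 0.40))
})

test_that("ladder runs in order, records deltas, and audits decisions", {
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  dat <- simulate_scenario(two_group_scenario(n = 500), seed = 157)
  lad <- run_ladder(dat, spec, "group")
  expect_s3_class(lad, "ladder_result")
  expect_equal(lad$attained, "residual")
  tab <- as.data.frame(lad)
  expect_equal(tab$level, c("configural", "metric", "scalar",
                            "factor_variance", "residual"))
  expect_true(all(diff(tab$df) > 0))
  # T_ML non-decreasing under added constraints (main branch)
  main <- c("configural", "metric", "scalar", "residual")
  tml <- vapply(lad$records[main], function(r) r$fit$T_ML, numeric(1))
  expect_true(all(diff(tml) > -1e-6))
  # audit: decisions recomputable from the stored deltas
  for (lv in c("metric", "scalar", "residual")) {
    r <- lad$records[[lv]]
    expect_equal(r$decision,
                 invariance_decision(r$delta$delta_cfi,
                                     r$delta$delta_rmsea, r$delta$p))
  }
  expect_error(run_ladder(dat, spec, "group",
                          levels = c("metric", "configural")), "order")
})

test_that("attained level is invariant to group label order", {
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  dat <- simulate_scenario(two_group_scenario(n = 400), seed = 163)
  lad1 <- run_ladder(dat, spec, "group",
                     levels = c("configural", "metric", "scalar"))
  # reverse group order by reordering rows
  ord <- order(dat$grouping$group, decreasing = TRUE)
  dat2 <- item_response_matrix(dat$values[ord, ],
                               item_ids = dat$item_ids,
                               grouping = dat$grouping[ord, , drop = FALSE])
  lad2 <- run_ladder(dat2, spec, "group",
                     levels = c("configural", "metric", "scalar"))
  expect_equal(lad1$attained, lad2$attained)
})

test_that("partial search frees the planted violation and reports freed sets", {
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  viol <- list(violation_spec("intercept", "phq2", 0.5, "B"))
  dat <- simulate_scenario(two_group_scenario(viol, n = 800), seed = 167)
  lad <- run_ladder(dat, spec, "group",
                    levels = c("configural", "metric", "scalar"))
  r <- lad$records$scalar
  expect_true(length(r$freed) >= 1)
  expect_true("phq2" %in% r$freed)
  expect_equal(lad$attained, "scalar")

  # invariant data: nothing freed at any retained level
  dat0 <- simulate_scenario(two_group_scenario(n = 800), seed = 173)
  lad0 <- run_ladder(dat0, spec, "group",
                     levels = c("configural", "metric", "scalar"))
  expect_equal(unname(unlist(lapply(lad0$records, `[[`, "freed"))),
               character(0))
})

test_that("modification indices track refitted chi-square drops", {
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  viol <- list(violation_spec("intercept", "phq5", 0.4, "B"))
  dat <- simulate_scenario(two_group_scenario(viol, n = 600), seed = 179)
  gdata <- psyvalid:::as_cfa_data(dat, spec$items, "group")
  fs <- fit_cfa(gdata, constrain_invariance(spec, c("A", "B"), "scalar"))
  mis <- vapply(paste0("phq", 1:9), function(it) {
    sp <- constrain_invariance(spec, c("A", "B"), "scalar",
                               freed = list(scalar = it))
    psyvalid:::modification_index(fs, sp)
  }, numeric(1))
  expect_equal(names(which.max(mis)), "phq5")
  # magnitude agrees with an actual refit for the top candidate
  sp5 <- constrain_invariance(spec, c("A", "B"), "scalar",
                              freed = list(scalar = "phq5"))
  f5 <- fit_cfa(gdata, sp5, start = fs$theta)
  expect_equal(unname(mis["phq5"]), fs$T_ML - f5$T_ML, tolerance = 0.15)
})

test_that("single-group input and unreachable levels fail loudly", {
  spec <- model_catalog(phq9_scale())$two_factor_correlated
  pop <- phq9_population()
  dat <- simulate_responses(pop, 300, seed = 181)
  expect_error(run_ladder(list(only = dat), spec), ">= 2 groups")
})
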