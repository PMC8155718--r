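test_that("read_responses parses CSV, handles missing codes and errors", {
  sdef <- phq9_scale()
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c("subject_id", "gender", sdef$items), collapse = ",")
  writeLines(c(hdr,
               paste(c("a", "f", rep("0", 9)), collapse = ","),
               paste(c("b", "m", "NA", rep("0", 8)), collapse = ",")),
             path)
  m <- read_responses(path, sdef)
  expect_equal(dim(m), c(2L, 9L))
  expect_equal(sum(m$values, na.rm = TRUE), 0)
  expect_equal(sum(is.na(m$values)), 1L)
  expect_equal(mean(is.na(m$values)), 1 / 18)
  expect_equal(m$grouping$gender, c("f", "m"))
  expect_equal(m$subject_ids, c("a", "b"))

  # TSV auto-detection round trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(sdef$items, collapse = "\t"),
               paste(rep("2", 9), collapse = "\t")), tsv)
  expect_equal(unname(unit_weighted_score(read_responses(tsv, sdef))), 18)

  # out-of-range code names the cell
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(sdef$items, collapse = ","),
               paste(c("4", rep("0", 8)), collapse = ",")), bad)
  expect_error(read_responses(bad, sdef), "out-of-range.*phq1")

  # missing item column
  short <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(sdef$items[-9], collapse = ","),
               paste(rep("0", 8), collapse = ",")), short)
  expect_error(read_responses(short, sdef), "phq9")
})

test_that("unit-weighted scores follow the complete-case convention", {
  sdef <- phq9_scale()
  v <- matrix(3, 4, 9, dimnames = list(NULL, sdef$items))
  v[2, ] <- 0
  v[3, 5] <- NA
  m <- item_response_matrix(v, item_ids = sdef$items)
  s <- unit_weighted_score(m)
  expect_equal(unname(s[1]), 27)   # scale maximum 9 x 3
  expect_equal(unname(s[2]), 0)
  expect_true(is.na(s[3]))         # any missing item -> missing score
  expect_error(unit_weighted_score(m, character(0)), "empty")

  # total = sum of subscale scores when nothing is missing
  set.seed(42)
  v2 <- matrix(sample(0:3, 90, TRUE), 10, 9,
               dimnames = list(NULL, sdef$items))
  m2 <- item_response_matrix(v2, item_ids = sdef$items)
  tot <- unit_weighted_score(m2)
  parts <- Reduce(`+`, lapply(sdef$subscales, function(it)
    unit_weighted_score(m2, it)))
  expect_equal(unname(tot), unname(parts))
})

test_that("complete_cases filters, keeps labels, and is idempotent", {
  sdef <- phq9_scale()
  v <- matrix(1, 5, 9, dimnames = list(NULL, sdef$items))
  v[1, 2] <- NA
  v[4, 7] <- NA
  m <- item_response_matrix(v, item_ids = sdef$items,
                            grouping = data.frame(g = letters[1:5]))
  cc <- complete_cases(m)
  expect_equal(nrow(cc$values), 3L)
  expect_equal(cc$grouping$g, c("b", "c", "e"))
  expect_identical(complete_cases(cc)$values, cc$values)
  # subset excluding the missing columns keeps everything
  expect_equal(nrow(complete_cases(m, sdef$items[c(1, 3)])$values), 5L)
  v[, ] <- NA
  expect_error(complete_cases(item_response_matrix(v)), "no complete cases")
})

test_that("missing_report summarises proportions, patterns and Little's test", {
  v <- matrix(0, 2, 5, dimnames = list(NULL, paste0("i", 1:5)))
  m <- item_response_matrix(v)
  rep0 <- missing_report(m)
  expect_equal(rep0$overall, 0)
  expect_equal(rep0$n_patterns, 1L)
  expect_equal(rep0$little$d2, 0)
  expect_equal(rep0$little$df, 0L)
  expect_equal(rep0$little$p, 1)

  v[1, 3] <- NA
  rep1 <- missing_report(item_response_matrix(v))
  expect_equal(rep1$overall, 0.1)
  expect_equal(rep1$n_patterns, 2L)

  v[, ] <- NA
  rep2 <- missing_report(item_response_matrix(v))
  expect_equal(rep2$overall, 1)
  expect_true(is.na(rep2$little$d2))

  expect_match(as.character(missing_report_json(rep1)), "overall")
})

test_that("Little's d2 is invariant to subject order and item relabeling", {
  set.seed(7)
  Sig <- diag(4) * 0.5 + 0.5
  Y <- MASS::mvrnorm(150, rep(0, 4), Sig)
  Y[matrix(runif(600) < 0.15, 150, 4)] <- NA
  Y <- Y[rowSums(!is.na(Y)) > 0, ]
  m <- item_response_matrix(Y, code_range = c(-Inf, Inf))
  t1 <- littles_mcar_test(m)
  perm_rows <- sample(nrow(Y))
  perm_cols <- c(3, 1, 4, 2)
  m2 <- item_response_matrix(Y[perm_rows, perm_cols],
                             code_range = c(-Inf, Inf))
  t2 <- littles_mcar_test(m2)
  expect_equal(t1$d2, t2$d2, tolerance = 1e-6)
  expect_equal(t1$df, t2$df)
})

test_that("Little's test has power against strong MAR missingness", {
  # missingness on item 1 imposed whenever item 2 is in its upper 30%
  set.seed(11)
  Sig <- diag(5) * 0.5 + 0.5
  rej <- 0
  B <- 60
  for (b in seq_len(B)) {
    Y <- MASS::mvrnorm(500, rep(0, 5), Sig)
    Y[Y[, 2] >= stats::quantile(Y[, 2], 0.7), 1] <- NA
    m <- item_response_matrix(Y, code_range = c(-Inf, Inf))
    if (littles_mcar_test(m)$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / B, 0.5)
})

test_that("scale definitions validate their partition and round-trip", {
  expect_error(scale_definition("X", c("a", "b"), list(s1 = "a")),
               "partition")
  expect_error(scale_definition("X", c("a", "b"),
                                list(s1 = c("a", "b"), s2 = "a")),
               "disjoint")
  sd1 <- scale_definition("X", c("a", "b", "c"),
                          list(s1 = c("a", "b"), s2 = "c"))
  expect_equal(sd1$degenerate, "s2")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scale_definition(phq9_scale(), path)
  rt <- read_scale_definition(path)
  expect_equal(rt$items, phq9_scale()$items)
  expect_equal(rt$subscales, phq9_scale()$subscales)
})
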