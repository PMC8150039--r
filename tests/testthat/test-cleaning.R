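test_that("cleaning cascade reproduces the emulated study's counts", {
  # default generator conditions: 743 starters, 38.9% abandoning, 6.6% of
  # completers failing a check -> 424 retained
  s <- generate_survey(survey_config(seed = 21))
  cl <- clean_dataset(s$data)
  r <- cl$report
  expect_equal(r$n_initial, 743)
  expect_equal(r$n_incomplete_removed, 289)
  expect_equal(r$n_careless_removed, 30)
  expect_equal(r$n_retained, 424)
  expect_equal(round(r$pct_incomplete, 1), 38.9)
  expect_equal(round(r$pct_careless_of_completers, 1), 6.6)
  expect_false(anyNA(cl$data))
})

test_that("clean data pass through unchanged and counts are conserved", {
  s <- generate_survey(survey_config(n_respondents = 40, dropout_rate = 0,
                                     careless_rate = 0, outlier_rate = 0,
                                     seed = 2))
  cl <- clean_dataset(s$data)
  expect_equal(cl$report$n_incomplete_removed, 0)
  expect_equal(cl$report$n_careless_removed, 0)
  expect_equal(cl$report$n_retained, 40)
  expect_identical(cl$data, s$data)

  for (seed in c(5, 6)) {
    s <- generate_survey(survey_config(n_respondents = 250, seed = seed))
    r <- clean_dataset(s$data)$report
    expect_equal(r$n_initial,
                 r$n_incomplete_removed + r$n_careless_removed + r$n_retained)
  }
})

test_that("careless removals match ground-truth labels among completers", {
  s <- generate_survey(survey_config(n_respondents = 500, seed = 31))
  cl <- clean_dataset(s$data)
  truth_careless <- sort(s$truth$labels$id[s$truth$labels$careless])
  expect_identical(sort(cl$report$removed_careless_ids), truth_careless)
})

test_that("sensitivity mode retains everyone", {
  s <- generate_survey(survey_config(n_respondents = 300, seed = 8))
  cl <- clean_dataset(s$data, sensitivity_mode = TRUE)
  expect_equal(cl$report$n_retained, 300)
  expect_equal(cl$report$n_incomplete_removed, 0)
  expect_true(cl$report$sensitivity_mode)
  expect_identical(cl$data, s$data)
})

test_that("missing attention-check columns raise a schema error", {
  s <- generate_survey(survey_config(n_respondents = 20, seed = 1))
  expect_error(clean_dataset(s$data[, setdiff(names(s$data), "check_1")]),
               "check")
})

test_that("scale scoring averages items with reverse coding", {
  sdef <- scale_definition("toy", c("a", "b"), reverse = "b")
  d <- tibble::tibble(a = c(3, 5, 1), b = c(3, 5, 2))
  expect_equal(score_scale(d, sdef), c(3, 3, 2.5))
  all3 <- tibble::tibble(a = rep(3, 4), b = rep(3, 4))
  expect_equal(score_scale(all3, sdef), rep(3, 4))

  # brute-force mean oracle on a random 11-item response
  set.seed(9)
  items <- paste0("q", 1:11)
  rev <- c("q2", "q7")
  d11 <- tibble::as_tibble(setNames(
    lapply(items, function(i) sample(1:5, 25, TRUE)), items))
  sdef11 <- scale_definition("s11", items, reverse = rev)
  oracle <- apply(d11, 1, function(r) {
    vals <- ifelse(items %in% rev, 6 - r, r)
    sum(vals) / 11
  })
  expect_equal(score_scale(d11, sdef11), unname(oracle), tolerance = 1e-12)

  # order invariance under item permutation
  perm <- sample(items)
  sdef_p <- scale_definition("s11p", perm, reverse = rev)
  expect_equal(score_scale(d11, sdef_p), score_scale(d11, sdef11))

  # missingness contract
  d11$q3[2] <- NA
  expect_error(score_scale(d11, sdef11), "missing")
  expect_true(is.na(score_scale(d11, sdef11, allow_missing = TRUE)[2]))
  expect_false(anyNA(score_scale(d11, sdef11, allow_missing = TRUE)[-2]))
})

test_that("weekly game time is 5 x weekday + 2 x weekend", {
  expect_equal(weekly_game_time(2, 4), 18)
  expect_equal(weekly_game_time(0, 0), 0)
  expect_equal(weekly_game_time(3, 5), 25)
  expect_error(weekly_game_time(-1, 2), "non-negative")
})

test_that("well-being reversal is the 6 - x involution", {
  expect_equal(reverse_wellbeing(1), 5)
  expect_equal(reverse_wellbeing(3), 3)
  expect_equal(reverse_wellbeing(4.5), 1.5)
  x <- runif(50, 1, 5)
  expect_equal(reverse_wellbeing(reverse_wellbeing(x)), x)
  expect_error(reverse_wellbeing(0.5), "\\[1, 5\\]")
})

test_that("playtime outliers are flagged by the 3-SD-or-zero rule", {
  base <- tibble::tibble(id = sprintf("p%03d", 1:101),
                         weekly_hours = c(rep(20, 100), 500),
                         session_minutes = rep(60, 101))
  expect_identical(flag_outliers(base), "p101")

  # zero-variance playtime: no SD flags
  same <- tibble::tibble(id = c("a", "b"), weekly_hours = c(10, 10),
                         session_minutes = c(90, 90))
  expect_identical(flag_outliers(same), character(0))

  # a zero-hours respondent is always flagged
  withzero <- base
  withzero$weekly_hours[1] <- 0
  expect_setequal(flag_outliers(withzero), c("p001", "p101"))

  # direct mean/SD oracle on a scored synthetic sample
  sc <- clean_scored(n = 300, seed = 77, outlier_rate = 0.05)
  w <- sc$weekly_hours; m <- sc$session_minutes
  oracle <- sc$id[w >= mean(w) + 3 * sd(w) | m >= mean(m) + 3 * sd(m) | w == 0]
  expect_setequal(flag_outliers(sc), oracle)
  expect_setequal(sc$id[sc$outlier], oracle)
})

test_that("scored dataset has every analysis column in range", {
  sc <- clean_scored(n = 200, seed = 55)
  for (v in c(default_predictors(), default_outcomes()))
    expect_true(all(sc[[v]] >= 1 & sc[[v]] <= 5), info = v)
  expect_s3_class(sc$gender, "factor")
  expect_identical(levels(sc$education), c("tertiary", "secondary"))
  expect_equal(sc$weekly_hours,
               5 * sc$weekday_hours + 2 * sc$weekend_hours)
  # composite scale equals the mean over its two constituent item sets
  inst <- load_instrument()
  items <- c(inst$scales$cvat2$items, inst$scales$icd$items)
  expect_equal(sc$cvat3, rowMeans(sc[, items]), tolerance = 1e-12)
})
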