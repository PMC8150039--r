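test_that("specification enumeration is an ordered Cartesian product", {
  sc <- clean_scored(n = 150, seed = 1)
  space <- build_default_space(sc)
  grid <- enumerate_specifications(space)
  expect_equal(nrow(grid), 972)
  expect_equal(length(space$outcomes), 3)
  expect_equal(length(space$predictors), 9)
  expect_equal(length(space$covariate_sets), 18)
  expect_equal(length(space$outlier_choices), 2)
  expect_equal(length(default_covariates()), 16)
  expect_false(anyDuplicated(grid[-1]) > 0)
  # deterministic lexicographic order: last axis varies fastest
  expect_identical(grid$outlier_choice[1:4],
                   c("include", "exclude", "include", "exclude"))
  expect_identical(grid$outcome[1], grid$outcome[2])

  tiny <- specification_space("y", "x", list(none = character(0)), "include")
  expect_equal(nrow(enumerate_specifications(tiny)), 1)
  four <- specification_space(c("y1", "y2"), c("x1", "x2"),
                              list(none = character(0), a = "age"))
  g4 <- enumerate_specifications(four)
  expect_equal(nrow(g4), 16)
  expect_equal(nrow(unique(g4[-1])), 16)

  expect_error(specification_space(character(0), "x",
                                   list(none = character(0))), "non-empty")
  expect_error(specification_space("y", "x", list(a = "x")), "covariate")
})

test_that("item-level space uses the 15 DSM-5 / ICD-11 items", {
  sc <- clean_scored(n = 150, seed = 1)
  space <- build_default_space(sc, item_level = TRUE)
  expect_equal(length(space$predictors), 15)
  expect_equal(nrow(enumerate_specifications(space)), 3 * 15 * 18 * 2)
  expect_true(all(grepl("^(cvat2|icd)_", space$predictors)))
})

test_that("bivariate specifications reduce to the Pearson correlation", {
  sc <- clean_scored(n = 300, seed = 3)
  res <- fit_specification(sc, "general_mental_health", "cvat2_11item",
                           character(0), "include")
  r <- cor(sc$general_mental_health, sc$cvat2_11item)
  expect_equal(res$beta, r, tolerance = 1e-10)
  expect_equal(res$dr2, res$beta^2, tolerance = 1e-10)
  expect_equal(res$r2, r^2, tolerance = 1e-10)

  # outcome identical to predictor: perfect fit
  sc$dup <- sc$cvat2_11item
  res2 <- suppressWarnings(
    fit_specification(sc, "dup", "cvat2_11item", character(0), "include"))
  expect_equal(res2$beta, 1, tolerance = 1e-10)
  expect_equal(res2$r2, 1, tolerance = 1e-10)
  expect_equal(res2$dr2, 1, tolerance = 1e-10)
})

test_that("semipartial R2 equals the refit difference with covariates", {
  sc <- clean_scored(n = 300, seed = 3)
  covs <- c("age", "gender", "mot_escapism")
  res <- fit_specification(sc, "life_satisfaction", "vat", covs, "include")
  # independent refit oracle
  d <- data.frame(y = scale(sc$life_satisfaction)[, 1],
                  x = scale(sc$vat)[, 1],
                  age = scale(sc$age)[, 1], gender = sc$gender,
                  mot_escapism = scale(sc$mot_escapism)[, 1])
  full <- summary(lm(y ~ x + age + gender + mot_escapism, d))$r.squared
  red <- summary(lm(y ~ age + gender + mot_escapism, d))$r.squared
  expect_equal(res$dr2, full - red, tolerance = 1e-10)
  expect_equal(res$r2, full, tolerance = 1e-10)
  # focal coefficient equals the oracle's standardized coefficient
  bet <- coef(lm(y ~ x + age + gender + mot_escapism, d))[["x"]]
  expect_equal(res$beta, bet, tolerance = 1e-10)
})

test_that("degenerate and pathological specifications are handled", {
  sc <- clean_scored(n = 120, seed = 6)
  sc$flat <- 3
  res <- fit_specification(sc, "life_satisfaction", "flat", character(0),
                           "include")
  expect_true(res$degenerate)
  sc$copy_age <- sc$age
  expect_error(fit_specification(sc, "life_satisfaction", "vat",
                                 c("age", "copy_age"), "include"),
               "collinear")
})

test_that("the full curve is deterministic and complete", {
  sc <- clean_scored(n = 200, seed = 10, outlier_rate = 0.05)
  space <- specification_space(
    default_outcomes(), c("vat", "odba"),
    list(none = character(0), age = "age", all = c("age", "mot_escapism")),
    c("include", "exclude"))
  r1 <- run_curve(sc, space, covariate_stats = FALSE)
  r2 <- run_curve(sc, space, covariate_stats = FALSE)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3 * 2 * 3 * 2)
  expect_identical(r1[, c("outcome", "predictor", "outlier_choice")],
                   enumerate_specifications(space)[, c("outcome", "predictor",
                                                       "outlier_choice")])
  # outlier exclusion actually changes the analysis n
  expect_lt(min(r1$n_used[r1$outlier_choice == "exclude"]),
            max(r1$n_used[r1$outlier_choice == "include"]))
})

test_that("curve summaries follow the central-model CI rule", {
  odd <- fake_results(beta = c(-0.5, -0.4, -0.1), se = c(0.05, 0.06, 0.04))
  s <- summarize_curve(odd, "x")
  expect_equal(s$median_beta, -0.4)
  expect_equal(s$ci_lo, -0.4 - qt(0.975, 100) * 0.06)
  expect_equal(s$ci_hi, -0.4 + qt(0.975, 100) * 0.06)
  expect_equal(s$min_beta, -0.5)
  expect_equal(s$max_beta, -0.1)

  even <- fake_results(beta = c(-0.6, -0.45, -0.35, -0.2),
                       se = c(0.05, 0.08, 0.06, 0.04))
  s2 <- summarize_curve(even, "x")
  expect_equal(s2$median_beta, mean(c(-0.45, -0.35)))
  expect_equal(s2$ci_lo, -0.4 - qt(0.975, 100) * 0.07)
  expect_equal(s2$ci_hi, -0.4 + qt(0.975, 100) * 0.07)

  one <- fake_results(beta = -0.3, se = 0.05)
  s3 <- summarize_curve(one, "x")
  expect_equal(s3$median_beta, -0.3)
  expect_equal(s3$n_models, 1)
  expect_equal(s3$ci_lo, one$ci_lo)

  expect_error(summarize_curve(odd, "absent"), "absent")
})

test_that("covariate summaries are extracted from the fitted models", {
  sc <- clean_scored(n = 250, seed = 12)
  space <- specification_space(
    c("life_satisfaction", "general_mental_health"), c("vat", "gko"),
    list(none = character(0), age = "age", gender = "gender"))
  res <- run_curve(sc, space, covariate_stats = TRUE)
  s_age <- summarize_curve(res, "age")
  expect_equal(s_age$n_models, 2 * 2 * 2)  # models containing age
  # oracle: standardized age coefficient of one specific model
  d <- sc[!sc$outlier, ]
  fit <- lm(scale(d$life_satisfaction)[, 1] ~ scale(d$vat)[, 1] +
              scale(d$age)[, 1])
  cf <- dplyr::bind_rows(res$coefs[res$outcome == "life_satisfaction" &
                                     res$predictor == "vat" &
                                     res$covariate_set == "age" &
                                     res$outlier_choice == "exclude"])
  expect_equal(cf$estimate, unname(coef(fit)[3]), tolerance = 1e-10)
  # gender enters unstandardized via the male indicator
  s_gender <- summarize_curve(res, "gender")
  expect_equal(s_gender$n_models, 8)
  cfg <- dplyr::bind_rows(res$coefs)[dplyr::bind_rows(res$coefs)$term ==
                                       "gender", ]
  expect_true(all(cfg$level == "gendermale"))
  expect_false(any(cfg$standardized))
})

test_that("negating the outcome negates every effect size", {
  sc <- clean_scored(n = 200, seed = 14, outlier_rate = 0.05)
  sc$neg <- 6 - sc$life_satisfaction  # mirrored outcome, still in [1, 5]
  space1 <- specification_space("life_satisfaction", c("vat", "icd11"),
                                list(none = character(0), age = "age"))
  space2 <- specification_space("neg", c("vat", "icd11"),
                                list(none = character(0), age = "age"))
  r1 <- run_curve(sc, space1, covariate_stats = FALSE)
  r2 <- run_curve(sc, space2, covariate_stats = FALSE)
  expect_equal(r2$beta, -r1$beta, tolerance = 1e-10)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)
  expect_equal(r2$r2, r1$r2, tolerance = 1e-10)
  expect_equal(r2$dr2, r1$dr2, tolerance = 1e-10)
  s1 <- summarize_curve(r1); s2 <- summarize_curve(r2)
  expect_equal(s2$median_beta, -s1$median_beta)
  expect_equal(s2$min_beta, -s1$max_beta)
})

test_that("pre-standardized inputs give identical results", {
  sc <- clean_scored(n = 180, seed = 16)
  sz <- sc
  for (v in c("life_satisfaction", "vat", "age"))
    sz[[v]] <- scale(sz[[v]])[, 1]
  space <- specification_space("life_satisfaction", "vat",
                               list(none = character(0), age = "age"))
  r1 <- run_curve(sc, space, covariate_stats = FALSE)
  r2 <- run_curve(sz, space, covariate_stats = FALSE)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-12)
  expect_equal(r1$se, r2$se, tolerance = 1e-12)
})

test_that("single-item effects stay near the hull of scale-level extremes", {
  # diagnostic: an item curve on matched data should not stray far outside
  # the range spanned by the scale-level operationalizations
  sc <- clean_scored(n = 400, seed = 71)
  sets <- list(none = character(0))
  scale_res <- run_curve(sc, specification_space(
    default_outcomes(), default_predictors(), sets, "include"),
    covariate_stats = FALSE)
  item_res <- run_curve(sc, specification_space(
    default_outcomes(),
    c(load_instrument()$scales$cvat2$items, load_instrument()$scales$icd$items),
    sets, "include"), covariate_stats = FALSE)
  expect_true(all(item_res$beta >= min(scale_res$beta) - 0.15 &
                  item_res$beta <= max(scale_res$beta) + 0.15))
})

test_that("analytic power follows the noncentral-t contract", {
  expect_equal(power_bivariate(424, 0), 0.05, tolerance = 1e-12)
  expect_gte(power_bivariate(424, 0.16), 0.90)
  expect_lt(power_bivariate(424, 0.16), 1)
  # monotone in |beta| and n
  expect_gt(power_bivariate(424, 0.2), power_bivariate(424, 0.16))
  expect_gt(power_bivariate(800, 0.16), power_bivariate(424, 0.16))
  expect_error(power_bivariate(3, 0.2), "n must")
  expect_error(power_bivariate(100, 1.2), "beta")
})

test_that("correlation matrix covers the analysis variables", {
  sc <- clean_scored(n = 200, seed = 18, outlier_rate = 0.05)
  cm <- correlation_matrix(sc)
  expect_true(all(c("vat", "odba", "life_satisfaction", "weekly_hours",
                    "mot_escapism") %in% rownames(cm)))
  expect_equal(diag(cm), setNames(rep(1, nrow(cm)), rownames(cm)))
  expect_equal(cm, t(cm))
  d <- sc[!sc$outlier, ]
  expect_equal(cm["vat", "life_satisfaction"],
               cor(d$vat, d$life_satisfaction), tolerance = 1e-12)
})
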