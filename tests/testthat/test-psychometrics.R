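test_that("CFA recovers loadings exactly from a population covariance", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  S <- tcrossprod(lam) + diag(1 - lam^2)
  fit <- fit_one_factor_cfa(S = S, n = 424)
  expect_lt(max(abs(fit$loadings - lam)), 1e-4)
  expect_lt(fit$fml, 1e-10)
  expect_equal(fit$chisq, 0, tolerance = 1e-6)
  expect_equal(fit$df, 4 * 5 / 2 - 8)
  expect_true(fit$converged)
})

test_that("independent items yield a factor explaining no shared variance", {
  # at the null the one-factor model is unidentified (a single-item "spike"
  # factor fits exactly as well as all-zero loadings), so the identifiable
  # implication is that the model-implied *shared* covariances vanish
  for (seed in 5:6) {
    set.seed(seed)
    x <- matrix(rnorm(50000 * 5), 50000, 5)
    fit <- fit_one_factor_cfa(x)
    implied_shared <- tcrossprod(fit$loadings)
    expect_lt(max(abs(implied_shared[upper.tri(implied_shared)])), 0.02)
    expect_lt(fit$fml, 1e-3)
    expect_lt(omega_from_fit(fit), 0.25)
  }
})

test_that("sign flips leave the discrepancy invariant and flip loadings", {
  x <- factor_items(300, c(0.7, 0.6, 0.8, 0.5), seed = 4)
  f1 <- fit_one_factor_cfa(x)
  f2 <- fit_one_factor_cfa(-x)
  expect_equal(f2$fml, f1$fml, tolerance = 1e-8)
  # the reported solution is normalized to a positive loading sum, so the
  # flipped data recover the same loadings
  expect_equal(f2$loadings, f1$loadings, tolerance = 1e-6)
  D <- diag(c(-1, 1, 1, 1))
  f3 <- fit_one_factor_cfa(S = D %*% cov(x) %*% D, n = nrow(x))
  expect_equal(f3$fml, f1$fml, tolerance = 1e-8)
  expect_equal(unname(abs(f3$loadings)), unname(abs(f1$loadings)),
               tolerance = 1e-5)
})

test_that("ML solution agrees with the factanal oracle", {
  x <- factor_items(500, c(0.75, 0.7, 0.65, 0.6, 0.55), seed = 12)
  R <- cor(x)
  ours <- fit_one_factor_cfa(S = R, n = nrow(x))
  fa <- stats::factanal(covmat = R, factors = 1, n.obs = nrow(x))
  expect_equal(unname(abs(ours$loadings)), unname(abs(as.numeric(fa$loadings))),
               tolerance = 2e-3)
})

test_that("fit indices hit their boundary identities", {
  lam <- rep(0.7, 5)
  S <- tcrossprod(lam) + diag(1 - lam^2)
  fit <- fit_one_factor_cfa(S = S, n = 424)
  idx <- compute_fit_indices(fit)
  expect_equal(idx$cfi, 1)
  expect_lt(idx$srmr, 1e-8)
  expect_equal(idx$rmsea, 0)

  # chisq = df  =>  RMSEA point estimate 0
  fake <- fit
  fake$chisq <- fit$df
  idx2 <- compute_fit_indices(fake)
  expect_equal(idx2$rmsea, 0)

  # df = 0: flagged, no interval
  lam3 <- c(0.8, 0.7, 0.6)
  S3 <- tcrossprod(lam3) + diag(1 - lam3^2)
  fit3 <- fit_one_factor_cfa(S = S3, n = 200)
  expect_equal(fit3$df, 0)
  idx3 <- compute_fit_indices(fit3)
  expect_true(idx3$df_zero_flag)
})

test_that("RMSEA interval matches a grid-search inversion oracle", {
  x <- factor_items(424, c(0.8, 0.7, 0.6, 0.55, 0.5, 0.45), seed = 3)
  fit <- fit_one_factor_cfa(x)
  idx <- compute_fit_indices(fit)
  grid <- seq(0, max(4 * fit$chisq, 50), by = 1e-4)
  cdf <- pchisq(fit$chisq, fit$df, ncp = grid)
  ncp_lo <- if (cdf[1] <= 0.95) 0 else grid[which(cdf <= 0.95)[1]]
  ncp_hi <- if (cdf[1] <= 0.05) 0 else grid[which(cdf <= 0.05)[1]]
  oracle <- sqrt(c(ncp_lo, ncp_hi) / (fit$df * (fit$n - 1)))
  expect_equal(idx$rmsea_ci, oracle, tolerance = 1e-3)
  expect_lte(idx$rmsea_ci[1], idx$rmsea)
  expect_gte(idx$rmsea_ci[2], idx$rmsea)
})

test_that("omega follows its closed form and invariances", {
  f <- list(loadings = rep(0.7, 5), uniquenesses = rep(0.51, 5))
  expect_equal(omega_from_fit(f), 12.25 / 14.80, tolerance = 1e-12)
  f0 <- list(loadings = rep(0.7, 5), uniquenesses = rep(1e-9, 5))
  expect_gt(omega_from_fit(f0), 0.999)
  expect_warning(
    expect_equal(omega_from_fit(list(loadings = rep(0, 4),
                                     uniquenesses = rep(1, 4))), 0),
    "zero")
  # invariant to item reordering and joint sign flip
  x <- factor_items(400, c(0.7, 0.65, 0.6, 0.55, 0.5), seed = 8)
  o1 <- omega_from_fit(fit_one_factor_cfa(x))
  o2 <- omega_from_fit(fit_one_factor_cfa(x[, c(3, 1, 5, 2, 4)]))
  o3 <- omega_from_fit(fit_one_factor_cfa(-x))
  expect_equal(o1, o2, tolerance = 1e-6)
  expect_equal(o1, o3, tolerance = 1e-6)
})

test_that("fitted omega approaches its population value", {
  x <- factor_items(1e4, rep(0.7, 5), seed = 20)
  om <- omega_from_fit(fit_one_factor_cfa(x))
  expect_lt(abs(om - 0.828), 0.02)
})

test_that("BCa interval behaves on degenerate and symmetric cases", {
  d <- matrix(rnorm(100), 100, 1)
  expect_warning(ci <- bca_ci(function(x) 1, d, B = 50, seed = 1),
                 "degenerate")
  expect_equal(unclass(ci)[1:2], c(1, 1))

  # symmetric statistic: BCa collapses to the percentile interval
  set.seed(2)
  d2 <- matrix(rnorm(200), 200, 1)
  ci2 <- bca_ci(function(x) mean(x), d2, B = 5000, seed = 7)
  expect_lt(abs(attr(ci2, "z0")), 0.08)
  expect_lt(abs(attr(ci2, "acceleration")), 0.03)
  # independent percentile-bootstrap oracle
  set.seed(99)
  perc <- quantile(replicate(5000, mean(sample(d2, replace = TRUE))),
                   c(0.025, 0.975))
  expect_lt(max(abs(unclass(ci2)[1:2] - perc)), 0.02 * sd(d2))
  expect_identical(ci2, bca_ci(function(x) mean(x), d2, B = 5000, seed = 7))
})

test_that("BCa endpoints agree with the boot-package oracle", {
  skip_if_not_installed("boot")
  set.seed(31)
  d <- matrix(rexp(150), 150, 1)   # skewed, so z0 and a matter
  ci <- bca_ci(function(x) mean(x), d, B = 4000, seed = 5)
  bt <- boot::boot(d[, 1], function(x, i) mean(x[i]), R = 4000)
  oracle <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_lt(max(abs(unclass(ci)[1:2] - oracle)), 0.05 * sd(d))
})

test_that("psychometric report covers every requested scale", {
  sc <- clean_scored(n = 250, seed = 40)
  inst <- load_instrument()
  sets <- list(icd11 = inst$scales$icd$items, gko = inst$scales$gko$items)
  rep <- psychometric_report(sc, sets, omega_ci = FALSE)
  expect_equal(rep$scale, c("icd11", "gko"))
  expect_true(all(rep$cfi >= 0 & rep$cfi <= 1))
  expect_true(all(rep$omega > 0.5 & rep$omega < 1))
  expect_true(all(rep$rmsea_lo <= rep$rmsea & rep$rmsea <= rep$rmsea_hi))
})

test_that("reverse-worded items are recoded before factoring", {
  sc <- clean_scored(n = 300, seed = 41)
  sets <- instrument_item_sets()
  expect_setequal(names(sets), c(default_predictors(), default_outcomes()))
  expect_equal(sets$general_mental_health$reverse,
               c("mhi_1", "mhi_2", "mhi_3"))
  rep <- psychometric_report(
    sc, sets[c("general_mental_health", "odba")], omega_ci = FALSE)
  expect_gt(rep$omega[rep$scale == "general_mental_health"], 0.6)
  # the behavioural-addiction scale is short with weak loadings by design
  expect_gt(rep$omega[rep$scale == "odba"], 0.3)
  expect_true(all(rep$cfi > 0.9))
  # skipping the recode leaves mixed-sign loadings and collapses omega
  raw <- psychometric_report(
    sc, list(gmh_raw = sets$general_mental_health$items), omega_ci = FALSE)
  expect_lt(raw$omega, 0.4)
})
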