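# Shared fixtures, all generated in code.

# clean mid-size survey (no contamination) scored for engine tests
clean_scored <- function(n = 400, seed = 101, d_effects = c(-0.40, -0.47, -0.33),
                         outlier_rate = 0) {
  cfg <- survey_config(n_respondents = n,
                       latent_corr = default_latent_corr(d_effects),
                       dropout_rate = 0, careless_rate = 0,
                       outlier_rate = outlier_rate, seed = seed)
  s <- generate_survey(cfg)
  score_dataset(clean_dataset(s$data)$data)
}

# one-factor continuous item data with known loadings
factor_items <- function(n, lambda, seed = 1) {
  set.seed(seed)
  f <- rnorm(n)
  x <- vapply(lambda, function(l) l * f + sqrt(1 - l^2) * rnorm(n), numeric(n))
  colnames(x) <- paste0("item_", seq_along(lambda))
  x
}

# small hand-made results table for summary-rule tests
fake_results <- function(beta, se, df = 100) {
  m <- length(beta)
  tibble::tibble(
    spec_id = seq_len(m), outcome = "y", predictor = "x",
    covariate_set = "none", outlier_choice = "include",
    beta = beta, se = se,
    ci_lo = beta - qt(0.975, df) * se, ci_hi = beta + qt(0.975, df) * se,
    p = 2 * pt(-abs(beta / se), df), r2 = beta^2, dr2 = beta^2,
    df = rep(df, m), n_used = df + 2L, degenerate = FALSE,
    coefs = replicate(m, NULL, simplify = FALSE))
}

# balanced crossed grid with known variance components
crossed_grid <- function(levels, sigma2, sigma2_e, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(lapply(levels, seq_len))
  names(grid) <- names(levels)
  y <- rnorm(nrow(grid), 0, sqrt(sigma2_e))
  for (cl in names(levels)) {
    u <- rnorm(levels[[cl]], 0, sqrt(sigma2[[cl]]))
    y <- y + u[grid[[cl]]]
  }
  grid$beta <- y
  for (cl in names(levels)) grid[[cl]] <- paste0(cl, grid[[cl]])
  grid$degenerate <- FALSE
  grid
}
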