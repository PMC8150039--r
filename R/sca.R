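#' Specification space
#'
#' The four decision axes of the multiverse: well-being outcome, dysregulated
#' gaming operationalization (scale score or single item), covariate set, and
#' whether playtime outliers are excluded.
#'
#' @param outcomes character vector of outcome column names.
#' @param predictors character vector of predictor column names.
#' @param covariate_sets named list of character vectors (possibly empty) of
#'   covariate names; names label the sets and must be distinct.
#' @param outlier_choices subset of `c("include", "exclude")`.
#' @return A `specification_space`.
#' @export
specification_space <- function(outcomes, predictors, covariate_sets,
                                outlier_choices = c("include", "exclude")) {
  if (!length(outcomes) || !length(predictors) || !length(covariate_sets) ||
      !length(outlier_choices))
    stop("every specification axis must be non-empty", call. = FALSE)
  labels <- vapply(covariate_sets, function(s)
    if (!length(s)) "none" else paste(sort(s), collapse = "+"), character(1))
  if (anyDuplicated(labels)) stop("covariate sets must be distinct", call. = FALSE)
  if (is.null(names(covariate_sets))) names(covariate_sets) <- labels
  for (p in predictors)
    for (s in covariate_sets)
      if (p %in% s) stop("predictor ", p, " appears in a covariate set",
                         call. = FALSE)
  structure(list(outcomes = outcomes, predictors = predictors,
                 covariate_sets = covariate_sets,
                 outlier_choices = match.arg(outlier_choices,
                                             c("include", "exclude"),
                                             several.ok = TRUE)),
            class = "specification_space")
}

#' @export
print.specification_space <- function(x, ...) {
  cat(sprintf("<specification_space> %d x %d x %d x %d = %d specifications\n",
              length(x$outcomes), length(x$predictors),
              length(x$covariate_sets), length(x$outlier_choices),
              length(x$outcomes) * length(x$predictors) *
                length(x$covariate_sets) * length(x$outlier_choices)))
  invisible(x)
}

#' Default specification space for a scored dataset
#'
#' Three well-being outcomes, nine dysregulated-gaming operationalizations
#' (or, in item-level mode, the 15 single items of the DSM-5 and ICD-11
#' instruments), 18 covariate sets (none, each of the 16 singletons, all 16),
#' and in/exclusion of playtime outliers.
#'
#' @param scored scored dataset from [score_dataset()].
#' @param item_level use single items as predictors?
#' @param instrument instrument definition.
#' @return A [specification_space()].
#' @export
build_default_space <- function(scored, item_level = FALSE,
                                instrument = load_instrument()) {
  preds <- if (item_level) {
    c(instrument$scales$cvat2$items, instrument$scales$icd$items)
  } else default_predictors()
  missing <- setdiff(c(preds, default_outcomes()), names(scored))
  if (length(missing))
    stop("scored dataset lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  covs <- default_covariates()
  sets <- c(list(none = character(0)),
            setNames(lapply(covs, identity), covs),
            list(all = covs))
  specification_space(default_outcomes(), preds, sets)
}

#' Enumerate all specifications
#'
#' Deterministic Cartesian product of the four axes in the order outcome,
#' predictor, covariate set, outlier choice (the last axis varies fastest).
#'
#' @param space a [specification_space()].
#' @return tibble with one row per specification (`spec_id`, `outcome`,
#'   `predictor`, `covariate_set`, `outlier_choice`).
#' @export
enumerate_specifications <- function(space) {
  stopifnot(inherits(space, "specification_space"))
  grid <- tidyr::expand_grid(
    outcome = space$outcomes,
    predictor = space$predictors,
    covariate_set = names(space$covariate_sets),
    outlier_choice = space$outlier_choices)
  grid$spec_id <- seq_len(nrow(grid))
  dplyr::relocate(grid, "spec_id")
}

#' Fit a single specification
#'
#' Ordinary least squares of the outcome on the focal predictor and the
#' covariates, on the subsample implied by the outlier choice. The outcome,
#' focal predictor and continuous covariates are z-scored within that
#' subsample; categorical covariates (gender, education) enter as indicator
#' contrasts and are left unstandardized. The semipartial `ΔR²` of the focal
#' predictor is the drop in multiple `R²` upon refitting without it.
#'
#' @param scored scored dataset (must carry an `outlier` logical column).
#' @param outcome,predictor column names.
#' @param covariates character vector of covariate names (possibly empty).
#' @param outlier_choice `"include"` or `"exclude"`.
#' @param covariate_stats also compute per-covariate coefficients and
#'   semipartial `ΔR²` (one extra refit per covariate)?
#' @return one-row tibble (`beta`, `se`, `ci_lo`, `ci_hi`, `p`, `r2`, `dr2`,
#'   `df`, `n_used`, and a `coefs` list-column of covariate statistics).
#' @export
fit_specification <- function(scored, outcome, predictor, covariates,
                              outlier_choice = "include",
                              covariate_stats = FALSE) {
  sub <- if (identical(outlier_choice, "exclude")) {
    scored[!scored$outlier, , drop = FALSE]
  } else scored
  sub <- sub[complete.cases(sub[, c(outcome, predictor, covariates),
                                drop = FALSE]), , drop = FALSE]
  k <- 1L + length(covariates)
  if (nrow(sub) <= k + 1L)
    stop("analysis subset too small for the requested model", call. = FALSE)
  if (sd(sub[[predictor]]) == 0)
    return(degenerate_result(outcome, predictor, covariates, outlier_choice))

  categorical <- intersect(covariates, c("gender", "education"))
  continuous <- setdiff(covariates, categorical)

  d <- data.frame(.y = zscore(sub[[outcome]]), .x = zscore(sub[[predictor]]))
  for (v in continuous) d[[v]] <- zscore(sub[[v]])
  for (v in categorical) d[[v]] <- droplevels(factor(sub[[v]]))
  rhs <- paste(c(".x", covariates), collapse = " + ")
  fit <- lm(as.formula(paste(".y ~", rhs)), data = d)
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit)))
    stop("rank-deficient model; collinear columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)

  beta <- cf[".x", "Estimate"]; se <- cf[".x", "Std. Error"]
  dfres <- fit$df.residual
  tcrit <- qt(0.975, dfres)
  r2 <- summary(fit)$r.squared
  refit <- function(drop_term) {
    keep <- setdiff(c(".x", covariates), drop_term)
    rhs0 <- if (length(keep)) paste(keep, collapse = " + ") else "1"
    summary(lm(as.formula(paste(".y ~", rhs0)), data = d))$r.squared
  }
  dr2 <- r2 - refit(".x")

  coefs <- NULL
  if (covariate_stats && length(covariates)) {
    rows <- lapply(covariates, function(v) {
      terms_v <- if (v %in% categorical) {
        grep(paste0("^", v), rownames(cf), value = TRUE)
      } else v
      # for categorical covariates report the first contrast (male /
      # secondary); sparse further levels stay in the model unreported
      tv <- terms_v[1]
      est <- cf[tv, "Estimate"]; sev <- cf[tv, "Std. Error"]
      tibble::tibble(term = v, level = tv, estimate = est, se = sev,
                     p = cf[tv, "Pr(>|t|)"],
                     standardized = !(v %in% categorical),
                     dr2 = r2 - refit(v))
    })
    coefs <- dplyr::bind_rows(rows)
  }

  tibble::tibble(
    outcome = outcome, predictor = predictor,
    covariate_set = if (!length(covariates)) "none" else
      paste(sort(covariates), collapse = "+"),
    outlier_choice = outlier_choice,
    beta = beta, se = se, ci_lo = beta - tcrit * se, ci_hi = beta + tcrit * se,
    p = cf[".x", "Pr(>|t|)"], r2 = r2, dr2 = dr2,
    df = dfres, n_used = nrow(sub), degenerate = FALSE,
    coefs = list(coefs))
}

degenerate_result <- function(outcome, predictor, covariates, outlier_choice) {
  tibble::tibble(
    outcome = outcome, predictor = predictor,
    covariate_set = if (!length(covariates)) "none" else
      paste(sort(covariates), collapse = "+"),
    outlier_choice = outlier_choice,
    beta = NA_real_, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    p = NA_real_, r2 = NA_real_, dr2 = NA_real_, df = NA_real_,
    n_used = NA_integer_, degenerate = TRUE, coefs = list(NULL))
}

#' Fit the whole specification curve
#'
#' One OLS fit per enumerated specification, in enumeration order, fully
#' deterministic. Degenerate specifications (zero-variance focal predictor)
#' are retained as flagged rows and excluded from summaries with a message.
#'
#' @param scored scored dataset.
#' @param space a [specification_space()].
#' @param covariate_stats compute per-covariate statistics (needed for
#'   covariate summary tables; roughly doubles the runtime)?
#' @return tibble of specification results (one row per specification).
#' @export
run_curve <- function(scored, space, covariate_stats = TRUE) {
  grid <- enumerate_specifications(space)
  res <- purrr::pmap(
    list(grid$outcome, grid$predictor, grid$covariate_set,
         grid$outlier_choice),
    function(o, p, cs_label, oc) {
      covs <- space$covariate_sets[[cs_label]]
      fit_specification(scored, o, p, covs, oc,
                        covariate_stats = covariate_stats)
    })
  out <- dplyr::bind_rows(res)
  out$spec_id <- grid$spec_id
  n_deg <- sum(out$degenerate)
  if (n_deg > 0)
    message(n_deg, " degenerate specification(s) skipped in summaries")
  dplyr::relocate(out, "spec_id")
}

#' Summarize a specification curve for one variable
#'
#' Median, minimum and maximum point estimate over every model containing the
#' variable, with the confidence interval of the model holding the
#' central-most estimate; with an even model count, the interval is built from
#' the mean of the two central estimates and the mean of their standard
#' errors. Also reports the median semipartial `ΔR²` and the share of models
#' significant at 0.05.
#'
#' @param results tibble from [run_curve()].
#' @param variable a predictor name, a covariate name (requires
#'   `covariate_stats = TRUE` in [run_curve()]), or `NULL` to pool the focal
#'   coefficients of all models (the curve's headline summary).
#' @param level confidence level (default 0.95).
#' @return one-row tibble (`variable`, `n_models`, `median_beta`, `ci_lo`,
#'   `ci_hi`, `min_beta`, `max_beta`, `median_dr2`, `frac_significant`).
#' @export
summarize_curve <- function(results, variable = NULL, level = 0.95) {
  results <- results[!results$degenerate, , drop = FALSE]
  if (is.null(variable) || variable %in% results$predictor) {
    rows <- if (is.null(variable)) results else
      results[results$predictor == variable, , drop = FALSE]
    if (!nrow(rows)) stop("variable absent from all models", call. = FALSE)
    est <- rows$beta; se <- rows$se; dfv <- rows$df
    dr2 <- rows$dr2; pv <- rows$p
    label <- variable %||% "(all models)"
  } else {
    cf <- dplyr::bind_rows(results$coefs)
    if (!nrow(cf) || !"term" %in% names(cf))
      stop("variable '", variable, "' absent from all models", call. = FALSE)
    cf <- cf[!is.na(cf$term) & cf$term == variable, , drop = FALSE]
    if (!nrow(cf))
      stop("variable '", variable, "' absent from all models", call. = FALSE)
    # degrees of freedom of the parent models that contain the covariate
    parents <- results[vapply(results$coefs, function(x)
      !is.null(x) && variable %in% x$term, logical(1)), , drop = FALSE]
    est <- cf$estimate; se <- cf$se; dfv <- parents$df
    dr2 <- cf$dr2; pv <- cf$p
    label <- variable
  }
  m <- length(est)
  ord <- order(est)
  alpha <- (1 - level) / 2
  if (m %% 2L == 1L) {
    c_idx <- ord[(m + 1L) / 2L]
    med <- est[c_idx]
    tcrit <- qt(1 - alpha, dfv[c_idx])
    ci <- med + c(-1, 1) * tcrit * se[c_idx]
  } else {
    c_idx <- ord[c(m / 2L, m / 2L + 1L)]
    med <- mean(est[c_idx])
    mse <- mean(se[c_idx])
    tcrit <- qt(1 - alpha, round(mean(dfv[c_idx])))
    ci <- med + c(-1, 1) * tcrit * mse
  }
  tibble::tibble(
    variable = label, n_models = m, median_beta = med,
    ci_lo = ci[1], ci_hi = ci[2],
    min_beta = min(est), max_beta = max(est),
    median_dr2 = median(dr2), frac_significant = mean(pv < 0.05))
}

#' Curve summary table over predictors and covariates
#'
#' Applies [summarize_curve()] to each dysregulated-gaming operationalization
#' and (when covariate statistics were collected) each covariate, mirroring a
#' per-variable summary table of median/min/max coefficients, the
#' median-model CI and median semipartial `ΔR²`.
#'
#' @param results tibble from [run_curve()].
#' @param space the [specification_space()] the results came from.
#' @return tibble, one row per variable.
#' @export
summarize_curve_table <- function(results, space) {
  vars <- space$predictors
  has_cov <- any(!vapply(results$coefs, is.null, logical(1)))
  if (has_cov)
    vars <- c(vars, unique(unlist(space$covariate_sets)))
  dplyr::bind_rows(lapply(vars, function(v) summarize_curve(results, v)))
}

#' Analytic power for a bivariate standardized slope
#'
#' Power of the two-sided t-test of a standardized regression coefficient in a
#' bivariate linear model, via the noncentral t distribution with
#' `df = n - 2` and noncentrality `beta * sqrt(n) / sqrt(1 - beta^2)`.
#'
#' @param n sample size (> 3).
#' @param beta true standardized slope, `|beta| < 1`.
#' @param alpha two-sided significance level.
#' @return power in `[0, 1]`.
#' @export
power_bivariate <- function(n, beta, alpha = 0.05) {
  if (!is_count(n) || n <= 3) stop("n must be an integer > 3", call. = FALSE)
  if (abs(beta) >= 1) stop("|beta| must be < 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  df <- n - 2
  ncp <- beta * sqrt(n) / sqrt(1 - beta^2)
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp) + pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Zero-order correlation matrix of the analysis variables
#'
#' Pearson correlations between all scale scores and continuous covariates,
#' computed on the outlier-excluded sample by default.
#'
#' @param scored scored dataset.
#' @param exclude_outliers drop flagged playtime outliers first?
#' @return correlation matrix.
#' @export
correlation_matrix <- function(scored, exclude_outliers = TRUE) {
  if (exclude_outliers) scored <- scored[!scored$outlier, , drop = FALSE]
  vars <- c(default_predictors(), default_outcomes(),
            setdiff(default_covariates(), c("gender", "education")))
  vars <- intersect(vars, names(scored))
  cor(as.matrix(scored[, vars]), use = "pairwise.complete.obs")
}
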