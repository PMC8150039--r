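#' Decompose curve variance over analytic-decision classes
#'
#' Fits the crossed random-effects null model
#' `beta_i = mu + u_outcome + u_predictor + u_covariate_set + u_outlier + e_i`
#' with independent zero-mean random effects by REML and converts the variance
#' components into intraclass correlation coefficients: each class's share of
#' the total effect-size variance across the specification curve. The headline
#' output is the shares normalized over the decision classes alone (summing to
#' 1, residual excluded); raw ICCs including the residual are also returned.
#'
#' Classes with a single level contribute a zero component; if all effect
#' sizes are identical every component is zero and a degenerate flag is set.
#' If REML fails to converge the Henderson/ANOVA method-of-moments estimate is
#' used with a warning (balanced grids only).
#'
#' @param results tibble from [run_curve()] (or any data frame with an effect
#'   column and one factor per class).
#' @param classes named character vector mapping class labels to columns of
#'   `results`; default: the four decision axes.
#' @param effect name of the effect-size column (default `"beta"`).
#' @return A `variance_components` tibble: `class`, `variance`, `icc`
#'   (share of total incl. residual), `share` (normalized over decision
#'   classes), plus attributes `residual`, `method`, `degenerate`.
#' @export
decompose_variance <- function(results,
                               classes = c(outcome = "outcome",
                                           predictor = "predictor",
                                           covariates = "covariate_set",
                                           subset = "outlier_choice"),
                               effect = "beta") {
  results <- as.data.frame(results)
  results <- results[!(results$degenerate %||% FALSE), , drop = FALSE]
  y <- results[[effect]]
  stopifnot(!is.null(y), length(y) >= 2L)
  fac <- lapply(classes, function(cl) factor(results[[cl]]))
  nlev <- vapply(fac, nlevels, integer(1))

  if (var(y) < 1e-20) {
    out <- tibble::tibble(class = names(classes), variance = 0, icc = 0,
                          share = 0)
    attr(out, "residual") <- 0
    attr(out, "method") <- "degenerate"
    attr(out, "degenerate") <- TRUE
    class(out) <- c("variance_components", class(out))
    return(out)
  }

  active <- names(classes)[nlev >= 2L]
  d <- data.frame(.y = y, fac)
  form <- as.formula(paste(".y ~ 1 +",
                           paste(sprintf("(1 | %s)", active), collapse = " + ")))
  comp <- setNames(numeric(length(classes)), names(classes))
  # convergence chatter on near-singular components is expected for grids
  # where a class contributes ~no variance; only hard errors trigger the
  # method-of-moments fallback
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.nlev.gtreq.5 = "ignore")))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    for (cl in active) comp[cl] <- vc$vcov[vc$grp == cl]
    resid_var <- vc$vcov[vc$grp == "Residual"]
    method <- "REML"
  } else {
    warning("REML did not converge; falling back to method-of-moments")
    mom <- mom_variance_components(d, active)
    comp[active] <- mom$components
    resid_var <- mom$residual
    method <- "method-of-moments"
  }
  comp <- pmax(comp, 0)
  if (!all(is.finite(c(comp, resid_var))))
    stop("variance components not estimable on this grid (no residual ",
         "replication)", call. = FALSE)
  total <- sum(comp) + resid_var
  shares <- if (sum(comp) > 0) comp / sum(comp) else comp
  out <- tibble::tibble(class = names(classes), variance = unname(comp),
                        icc = unname(comp / total), share = unname(shares))
  attr(out, "residual") <- resid_var
  attr(out, "method") <- method
  attr(out, "degenerate") <- FALSE
  class(out) <- c("variance_components", class(out))
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components> method:", attr(x, "method"), "\n")
  NextMethod()
  cat(sprintf("residual variance: %.6g\n", attr(x, "residual")))
  invisible(x)
}

#' Henderson / ANOVA method-of-moments variance components
#'
#' For a balanced crossed design with additive random effects and one
#' observation per cell, the expected mean square of each main effect is
#' `sigma2_e + (N / a_k) * sigma2_k`; solving gives the classic ANOVA
#' estimator (truncated at zero). Used as the independent cross-check and the
#' fallback for [decompose_variance()].
#'
#' @param d data frame with response `.y` and one factor column per class.
#' @param active character vector of factor column names.
#' @return list with `components` (named) and `residual`.
#' @export
mom_variance_components <- function(d, active) {
  counts <- vapply(active, function(cl) nlevels(d[[cl]]), integer(1))
  if (nrow(d) != prod(counts) ||
      nrow(unique(d[active])) != prod(counts))
    stop("method-of-moments estimator requires a complete balanced grid",
         call. = FALSE)
  form <- as.formula(paste(".y ~", paste(active, collapse = " + ")))
  tab <- anova(lm(form, data = d))
  ms <- tab$`Mean Sq`
  names(ms) <- rownames(tab)
  mse <- ms[["Residuals"]]
  N <- nrow(d)
  comps <- vapply(active, function(cl) {
    max((ms[[cl]] - mse) * counts[[cl]] / N, 0)
  }, numeric(1))
  list(components = comps, residual = mse)
}

#' Re-run the decomposition without one predictor
#'
#' Filters the curve to models not using the given predictor operationalization
#' and decomposes the variance of the remaining effect sizes; used to test
#' whether an anomalous operationalization inflates the predictor share.
#'
#' @param results tibble from [run_curve()].
#' @param excluded predictor name to drop.
#' @param ... passed to [decompose_variance()].
#' @return A `variance_components` tibble.
#' @export
rerun_without_predictor <- function(results, excluded, ...) {
  if (!excluded %in% results$predictor)
    stop("predictor '", excluded, "' not present in the results", call. = FALSE)
  kept <- results[results$predictor != excluded, , drop = FALSE]
  if (!length(unique(kept$predictor)))
    stop("removing '", excluded, "' empties the predictor class", call. = FALSE)
  decompose_variance(kept, ...)
}
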