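#' Fit a one-factor confirmatory factor model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p` over loadings `lambda`
#' and uniquenesses `theta` with the factor variance fixed at 1, so
#' `Sigma = lambda lambda' + diag(theta)`. Optimization uses analytic
#' gradients from a principal-axis start plus three random restarts; the best
#' solution within a tie tolerance of 1e-10 is kept. `chisq = (n - 1) * F_ML`,
#' `df = p(p+1)/2 - 2p`.
#'
#' @param items n x p matrix/data frame of (treated-as-continuous) responses;
#'   alternatively pass a sample covariance matrix `S` with sample size `n`.
#' @param S optional p x p sample covariance matrix (used if `items` is NULL).
#' @param n sample size (required with `S`).
#' @param restarts number of random restarts beyond the principal-axis start.
#' @param seed seed for the random restarts.
#' @return A `cfa_fit`: loadings, uniquenesses, `fml`, `chisq`, `df`, `n`,
#'   `S`, `sigma` (model-implied covariance), `converged`.
#' @export
fit_one_factor_cfa <- function(items = NULL, S = NULL, n = NULL,
                               restarts = 3L, seed = 1L) {
  if (!is.null(items)) {
    items <- as.matrix(items)
    stopifnot(ncol(items) >= 3L, nrow(items) > ncol(items))
    n <- nrow(items)
    S <- cov(items)
  } else {
    stopifnot(!is.null(S), !is.null(n))
    S <- as.matrix(S)
  }
  p <- ncol(S)
  stopifnot(p >= 3L)
  ldetS <- determinant(S, logarithm = TRUE)$modulus[1]
  if (!is.finite(ldetS)) stop("singular sample covariance matrix", call. = FALSE)

  fml <- function(par) {
    l <- par[1:p]; th <- par[(p + 1):(2 * p)]
    Sig <- tcrossprod(l) + diag(th, p)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S) - ldetS - p
  }
  grad <- function(par) {
    l <- par[1:p]; th <- par[(p + 1):(2 * p)]
    Sig <- tcrossprod(l) + diag(th, p)
    Sinv <- chol2inv(chol(Sig))
    A <- Sinv - Sinv %*% S %*% Sinv
    c(2 * drop(A %*% l), diag(A))
  }

  # principal-axis start: first eigenvector of S scaled to its eigenvalue
  ev <- eigen(S, symmetric = TRUE)
  l0 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 1e-6))
  starts <- list(c(l0, pmax(diag(S) - l0^2, 0.05 * diag(S))))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  for (r in seq_len(restarts)) {
    lr <- runif(p, 0.2, 0.9) * sqrt(diag(S)) * sample(c(-1, 1), 1)
    starts[[r + 1L]] <- c(lr, pmax(diag(S) - lr^2, 0.1 * diag(S)))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  best <- NULL
  for (st in starts) {
    opt <- nlminb(st, fml, grad,
                  lower = c(rep(-Inf, p), rep(1e-8, p)),
                  control = list(rel.tol = 1e-14, iter.max = 1000L))
    if (is.null(best) || opt$objective < best$objective - 1e-10) best <- opt
  }
  l <- best$par[1:p]
  if (sum(l) < 0) l <- -l     # sign convention: positive loading sum
  th <- best$par[(p + 1):(2 * p)]
  fml_val <- max(best$objective, 0)
  df <- p * (p + 1) / 2 - 2 * p
  structure(
    list(loadings = l, uniquenesses = th, fml = fml_val,
         chisq = (n - 1) * fml_val, df = df,
         p_value = if (df > 0) pchisq((n - 1) * fml_val, df,
                                      lower.tail = FALSE) else NA_real_,
         n = n, S = S, sigma = tcrossprod(l) + diag(th, p),
         converged = best$convergence == 0),
    class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit> p = %d, n = %d, chisq = %.3f (df = %g), F_ML = %.6f%s\n",
              length(x$loadings), x$n, x$chisq, x$df, x$fml,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Independence (baseline) model fit
#'
#' Zero covariances with free variances: `Sigma_b = diag(diag(S))`, giving
#' `F_ML = sum(log s_jj) - log|S|` and `df = p(p-1)/2`.
#'
#' @param S sample covariance matrix.
#' @param n sample size.
#' @return list with `chisq`, `df`.
#' @export
baseline_fit <- function(S, n) {
  S <- as.matrix(S)
  p <- ncol(S)
  fml <- sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus[1]
  list(chisq = (n - 1) * max(fml, 0), df = p * (p - 1) / 2)
}

#' Fit indices for a covariance-structure model
#'
#' CFI against the independence baseline, RMSEA with a 90% confidence interval
#' from inverting the noncentral chi-square distribution, and SRMR over
#' standardized residuals including the diagonal. With `df = 0` the RMSEA is
#' reported as 0 with a caution flag (point-identified model).
#'
#' @param fit a `cfa_fit`.
#' @param baseline optional baseline fit (list with `chisq`, `df`); defaults to
#'   the independence model on `fit$S`.
#' @param ci_level confidence level for the RMSEA interval (default 0.90).
#' @return list with `cfi`, `rmsea`, `rmsea_ci` (lower, upper), `srmr`,
#'   `df_zero_flag`.
#' @export
compute_fit_indices <- function(fit, baseline = NULL, ci_level = 0.90) {
  if (is.null(baseline)) baseline <- baseline_fit(fit$S, fit$n)
  chisq <- fit$chisq; df <- fit$df; n <- fit$n
  d <- max(chisq - df, 0)
  db <- max(baseline$chisq - baseline$df, 0)
  cfi <- 1 - d / max(db, d, .Machine$double.eps)

  if (df > 0) {
    rmsea <- sqrt(d / (df * (n - 1)))
    alpha <- (1 - ci_level) / 2
    lo <- ncp_search(chisq, df, 1 - alpha)   # ncp with obs at upper percentile
    hi <- ncp_search(chisq, df, alpha)
    ci <- sqrt(c(lo, hi) / (df * (n - 1)))
    flag <- FALSE
  } else {
    rmsea <- 0; ci <- c(0, 0); flag <- TRUE
  }

  Sv <- fit$S; Mv <- fit$sigma
  s <- sqrt(diag(Sv))
  res <- (Sv - Mv) / tcrossprod(s)
  srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  list(cfi = cfi, rmsea = rmsea, rmsea_ci = ci, srmr = srmr,
       df_zero_flag = flag)
}

# find the noncentrality parameter at which `chisq` sits at the given
# percentile of the noncentral chi-square distribution; 0 when impossible
ncp_search <- function(chisq, df, prob) {
  if (pchisq(chisq, df, ncp = 0) <= prob) return(0)
  upper <- max(chisq * 2, df * 4, 10)
  while (pchisq(chisq, df, ncp = upper) > prob) upper <- upper * 2
  uniroot(function(ncp) pchisq(chisq, df, ncp = ncp) - prob,
          c(0, upper), tol = 1e-9)$root
}

#' Coefficient omega from a one-factor fit
#'
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta)`: the proportion of
#' scale-score variance attributable to the common factor.
#'
#' @param fit a `cfa_fit` (or any list with `loadings` and `uniquenesses`).
#' @return omega in `[0, 1)`.
#' @export
omega_from_fit <- function(fit) {
  ls <- sum(fit$loadings)
  if (abs(ls) < .Machine$double.eps^0.5) {
    warning("all loadings are zero; omega = 0")
    return(0)
  }
  ls^2 / (ls^2 + sum(fit$uniquenesses))
}

#' Psychometric report over scale operationalizations
#'
#' One-factor CFA, fit indices and omega (with a BCa bootstrap CI) for each
#' named set of item columns, in the shape of a scale-validation table
#' (chi-square, df, p, CFI, RMSEA [90% CI], SRMR, omega [95% CI]).
#'
#' @param data cleaned respondent table with item columns.
#' @param item_sets named list; each element is either a character vector of
#'   item columns or a list with `items` and `reverse` (reverse-coded items
#'   are recoded to `6 - response` before factoring, so all items point in
#'   the scored direction).
#' @param B bootstrap replicates for the omega interval (default 1000).
#' @param seed bootstrap seed.
#' @param omega_ci compute the bootstrap interval? (slowest part; disable for
#'   quick looks).
#' @return tibble, one row per item set.
#' @export
psychometric_report <- function(data, item_sets, B = 1000L, seed = 1L,
                                omega_ci = TRUE) {
  rows <- lapply(names(item_sets), function(nm) {
    set <- item_sets[[nm]]
    if (!is.list(set)) set <- list(items = set, reverse = character(0))
    items <- as.matrix(data[, set$items, drop = FALSE])
    rev <- set$items %in% set$reverse
    items[, rev] <- 6 - items[, rev, drop = FALSE]
    fit <- fit_one_factor_cfa(items)
    idx <- compute_fit_indices(fit)
    om <- omega_from_fit(fit)
    if (omega_ci) {
      ci <- bca_ci(function(d) omega_from_fit(fit_one_factor_cfa(d)),
                   items, B = B, seed = derive_seed(seed, nm),
                   jack_groups = 40L)
    } else ci <- c(NA_real_, NA_real_)
    tibble::tibble(
      scale = nm, p_items = ncol(items), chisq = fit$chisq, df = fit$df,
      p_value = fit$p_value, cfi = idx$cfi, rmsea = idx$rmsea,
      rmsea_lo = idx$rmsea_ci[1], rmsea_hi = idx$rmsea_ci[2],
      srmr = idx$srmr, omega = om, omega_lo = ci[1], omega_hi = ci[2])
  })
  dplyr::bind_rows(rows)
}

#' Item sets (with reverse-coding) for the instrument's psychometric report
#'
#' One entry per dysregulated-gaming operationalization and well-being scale,
#' carrying the reverse-coded item ids so [psychometric_report()] factors all
#' items in the scored direction.
#'
#' @param instrument instrument definition from [load_instrument()].
#' @return named list of `list(items, reverse)`.
#' @export
instrument_item_sets <- function(instrument = load_instrument()) {
  sets <- lapply(instrument$predictors, function(p)
    list(items = p$items, reverse = p$reverse))
  for (nm in names(instrument$outcomes)) {
    sc <- instrument$scales[[instrument$outcomes[[nm]]$scale]]
    sets[[nm]] <- list(items = sc$items, reverse = sc$reverse)
  }
  sets
}
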