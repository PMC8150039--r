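#' @importFrom rlang %||% .data
#' @importFrom stats cov cor sd median quantile qnorm pnorm dnorm qt pt rnorm
#'   runif rbinom rlnorm rgamma lm coef vcov resid pchisq qchisq uniroot nlminb
#'   setNames var complete.cases as.formula anova aov model.matrix optim
#'   rmultinom
#' @importFrom utils head write.csv
NULL

# z-score a numeric vector using the sample mean/sd of the values given;
# constant vectors map to 0 (degenerate, caller decides whether that is legal)
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x == round(x)

# deterministic 32-bit sub-seed derived from a master seed and a stream label,
# so independent stages of the pipeline draw from independent streams
derive_seed <- function(seed, stream) {
  stopifnot(is_count(abs(seed)))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}
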