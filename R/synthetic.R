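#' Discretize a latent value onto a 1-5 Likert response
#'
#' Graded-response-style discretization: the response is `1 +` the number of
#' thresholds strictly below the latent value.
#'
#' @param latent numeric vector of latent item values.
#' @param thresholds strictly increasing numeric vector of length 4
#'   (standard-normal cut points).
#' @return integer vector of responses in 1..5.
#' @examples
#' likert_discretize(c(-10, 0, 10), c(-1.5, -0.5, 0.5, 1.5))
#' @export
likert_discretize <- function(latent, thresholds) {
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    stop("thresholds must be 4 strictly increasing cut points", call. = FALSE)
  as.integer(1L + findInterval(latent, thresholds, left.open = TRUE))
}

# ---- attenuation bookkeeping -------------------------------------------------
#
# Items are generated as y* = g*lambda*F + sqrt(1-lambda^2)*eps and then
# discretized, so a mean score over discretized items correlates with F at
# a < 1 ("attenuation"). Univariate item moments are exact; covariances
# between two discretized items with latent correlation rho use the Hermite
# expansion cov = sum_m rho^m/m! * A_m(tau_j) A_m(tau_k), truncated at m = 3
# (the omitted terms are < 1e-3 for the loadings used here).

hermite_A <- function(tau) {
  # A_m(tau) = E[ 1{X > t} He_m(X) ] summed over the four thresholds
  c(sum(dnorm(tau)),
    sum(tau * dnorm(tau)),
    sum((tau^2 - 1) * dnorm(tau)))
}

item_variance_exact <- function(tau) {
  p <- pnorm(tau, lower.tail = FALSE)       # P(X > tau_k)
  v <- sum(p * (1 - p))
  for (k in seq_len(3L)) for (l in (k + 1L):4L) v <- v + 2 * p[l] * (1 - p[k])
  v
}

# Per-score attenuation summary for a set of items.
# gen_sign: +-1 sign with which each item's latent loads on the factor
# score_sign: +1 for items entered as-is, -1 for reverse-coded (6 - r) items
score_moments <- function(lambda, tau_list, gen_sign, score_sign) {
  p <- length(lambda)
  A <- vapply(tau_list, hermite_A, numeric(3))          # 3 x p
  vars <- vapply(tau_list, item_variance_exact, numeric(1))
  l_signed <- gen_sign * lambda
  # U_m = sum_j s_j * (g_j lambda_j)^m * A_m(tau_j), the score-level Hermite
  # coefficients used for both within-score variance and cross-score covariance
  U <- vapply(1:3, function(m) sum(score_sign * l_signed^m * A[m, ]), numeric(1))
  # within-score variance: exact diagonal + Hermite off-diagonal
  v <- sum(vars)
  for (j in seq_len(p)) for (k in seq_len(p)) {
    if (j == k) next
    rho <- l_signed[j] * l_signed[k]
    v <- v + score_sign[j] * score_sign[k] *
      sum(rho^(1:3) / factorial(1:3) * A[, j] * A[, k])
  }
  var_score <- v / p^2
  cov_f <- sum(score_sign * l_signed * A[1, ]) / p      # cov(score, F)
  list(var = var_score, sd = sqrt(var_score), cov_f = cov_f,
       attenuation = cov_f / sqrt(var_score), U = U, p = p)
}

# Observed correlation between two scores as a function of the latent factor
# correlation r; `flip` carries score-level reversals (e.g. depressive mood
# reversed into absence of depressive mood).
observed_from_latent <- function(r, mx, my, flip = 1) {
  flip * sum(r^(1:3) / factorial(1:3) * mx$U * my$U) / (mx$p * my$p * mx$sd * my$sd)
}

# Solve observed_from_latent(r) = target for r (monotone on (-1, 1)).
latent_from_observed <- function(target, mx, my, flip = 1) {
  f <- function(r) observed_from_latent(r, mx, my, flip) - target
  lo <- f(-0.995); hi <- f(0.995)
  if (lo * hi > 0)
    stop("target observed correlation ", target,
         " is unattainable at the configured reliabilities", call. = FALSE)
  uniroot(f, c(-0.995, 0.995), tol = 1e-10)$root
}

# ---- configuration -----------------------------------------------------------

#' Configuration for the synthetic survey generator
#'
#' Defines the study conditions emulated by [generate_survey()]: sample size,
#' true standardized associations between the dysregulation construct (D) and
#' the three well-being constructs (W1 general mental health, W2 absence of
#' depressive mood, W3 life satisfaction), per-scale factor loadings and Likert
#' thresholds, covariate distributions, and contamination rates.
#'
#' Defaults follow the emulated survey: 743 starters of whom 38.9% abandon,
#' 6.6% of completers answer carelessly, and ~5% of the cleaned sample report
#' extreme playtime; D-W effects default to -0.40 / -0.47 / -0.33, the observed
#' per-outcome medians of the emulated study.
#'
#' @param n_respondents number of people who begin the survey.
#' @param latent_corr 4x4 symmetric correlation matrix over (D, W1, W2, W3).
#'   With `effects_are_observed = TRUE` (default) entries are targets for the
#'   *observed* correlations between the reference dysregulation score
#'   (CVAT-2 11-item) / well-being scores, and the generator inflates the
#'   latent correlations to undo Likert-and-reliability attenuation; with
#'   `FALSE` the entries are used as latent correlations directly.
#' @param effects_are_observed interpret `latent_corr` on the observed scale?
#' @param scale_specs named list per scale: `lambda` (per-item loadings in
#'   (0,1)) and `thresholds` (4 increasing standard-normal cut points).
#' @param covariate_spec list of covariate distribution settings; see
#'   [default_covariate_spec()].
#' @param dropout_rate fraction abandoning the survey at a random page.
#' @param careless_rate fraction of completers producing patterned responses
#'   and failing at least one attention check.
#' @param outlier_rate fraction of attentive completers with extreme playtime.
#' @param seed integer seed; generation is fully reproducible.
#' @param instrument instrument definition from [load_instrument()].
#' @return A `survey_config` list, validated.
#' @export
survey_config <- function(n_respondents = 743,
                          latent_corr = default_latent_corr(),
                          effects_are_observed = TRUE,
                          scale_specs = NULL,
                          covariate_spec = default_covariate_spec(),
                          dropout_rate = 289 / 743,
                          careless_rate = 30 / 454,
                          outlier_rate = 22 / 424,
                          seed = 1L,
                          instrument = load_instrument()) {
  stopifnot(is_count(n_respondents), n_respondents >= 1)
  rates <- c(dropout_rate, careless_rate, outlier_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  latent_corr <- as.matrix(latent_corr)
  if (!isTRUE(all.equal(latent_corr, t(latent_corr))) ||
      any(abs(diag(latent_corr) - 1) > 1e-12))
    stop("latent_corr must be symmetric with unit diagonal", call. = FALSE)
  if (min(eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("latent_corr must be positive semi-definite", call. = FALSE)
  if (is.null(scale_specs)) scale_specs <- default_scale_specs(instrument)
  for (nm in names(scale_specs)) {
    sp <- scale_specs[[nm]]
    if (any(sp$lambda <= 0 | sp$lambda >= 1))
      stop("loadings for ", nm, " must lie in (0, 1)", call. = FALSE)
    if (length(sp$thresholds) != 4L || any(diff(sp$thresholds) <= 0))
      stop("thresholds for ", nm, " must be 4 strictly increasing values",
           call. = FALSE)
    if (length(sp$lambda) != length(instrument$scales[[nm]]$items))
      stop("loading vector length mismatch for scale ", nm, call. = FALSE)
  }
  structure(
    list(n_respondents = as.integer(n_respondents), latent_corr = latent_corr,
         effects_are_observed = isTRUE(effects_are_observed),
         scale_specs = scale_specs, covariate_spec = covariate_spec,
         dropout_rate = dropout_rate, careless_rate = careless_rate,
         outlier_rate = outlier_rate, seed = as.integer(seed),
         instrument = instrument),
    class = "survey_config")
}

#' @rdname survey_config
#' @export
default_latent_corr <- function(d_effects = c(-0.40, -0.47, -0.33),
                                w_corr = c(0.55, 0.45, 0.40)) {
  m <- diag(4)
  dimnames(m) <- rep(list(c("D", "W1", "W2", "W3")), 2)
  m["D", c("W1", "W2", "W3")] <- m[c("W1", "W2", "W3"), "D"] <- d_effects
  m["W1", "W2"] <- m["W2", "W1"] <- w_corr[1]
  m["W1", "W3"] <- m["W3", "W1"] <- w_corr[2]
  m["W2", "W3"] <- m["W3", "W2"] <- w_corr[3]
  m
}

#' @rdname survey_config
#' @export
default_scale_specs <- function(instrument = load_instrument()) {
  gaming_tau <- c(-0.5, 0.5, 1.5, 2.5)     # skewed-low endorsement
  wellbeing_tau <- c(-2.2, -1.2, -0.3, 0.7) # skewed-high well-being
  lam <- function(sc, l) rep(l, length(instrument$scales[[sc]]$items))
  specs <- list(
    vat   = list(lambda = lam("vat", 0.65),  thresholds = gaming_tau),
    cvat2 = list(lambda = lam("cvat2", 0.65), thresholds = gaming_tau),
    icd   = list(lambda = lam("icd", 0.65),  thresholds = gaming_tau),
    odba  = list(lambda = c(0.50, 0.50, 0.45, 0.28), thresholds = gaming_tau),
    gko   = list(lambda = lam("gko", 0.68),  thresholds = gaming_tau),
    mhi   = list(lambda = lam("mhi", 0.70),  thresholds = wellbeing_tau),
    adm   = list(lambda = lam("adm", 0.75),  thresholds = wellbeing_tau),
    swl   = list(lambda = lam("swl", 0.70),  thresholds = wellbeing_tau)
  )
  specs
}

#' @rdname survey_config
#' @export
default_covariate_spec <- function() {
  list(
    age = list(min = 16, shape = 1.15, scale = 7.2),
    gender = list(levels = c("female", "male", "other"),
                  probs = c(113, 307, 4) / 424,
                  # additive shift of each well-being latent for males,
                  # mirroring the male contrast of the emulated sample
                  male_shift = c(W1 = 0.25, W2 = 0.25, W3 = 0.05)),
    education = list(levels = c("secondary", "tertiary"), probs = c(0.35, 0.65)),
    playtime = list(weekly_meanlog = 2.96, weekly_sdlog = 0.55,
                    d_loading = 0.25,       # log weekly hours ~ weak f(D)
                    weekday_share = 0.60, share_noise = 0.08),
    session = list(meanlog = 4.90, sdlog = 0.45, d_loading = 0.15),
    # motivations / need satisfactions: mean score, sd, and weak loadings on
    # the dysregulation (D) and average well-being (W) latents
    likert_covariates = list(
      mot_habit       = list(mean = 3.7, sd = 0.85, d = 0.25, w = 0.00),
      mot_narrative   = list(mean = 4.0, sd = 0.65, d = 0.05, w = 0.00),
      mot_pastime     = list(mean = 3.1, sd = 0.90, d = 0.25, w = -0.10),
      mot_performance = list(mean = 3.8, sd = 0.60, d = 0.10, w = 0.10),
      mot_reactivity  = list(mean = 4.3, sd = 0.55, d = 0.05, w = 0.05),
      mot_social      = list(mean = 3.4, sd = 0.95, d = 0.15, w = 0.10),
      mot_escapism    = list(mean = 3.9, sd = 0.65, d = 0.30, w = -0.15),
      mot_agency      = list(mean = 3.7, sd = 0.60, d = 0.05, w = 0.00),
      need_autonomy   = list(mean = 3.8, sd = 0.55, d = 0.05, w = 0.00),
      need_competence = list(mean = 3.9, sd = 0.60, d = 0.05, w = 0.10),
      need_relatedness= list(mean = 3.3, sd = 0.90, d = 0.10, w = 0.05)
    )
  )
}

# Attenuation table over all named scores the analysis uses.
#
# Items worded against their construct are generated from -F with mirrored
# thresholds -rev(tau) (see generate_survey), which makes the scored
# (re-reversed) item exactly equal in distribution to a positively worded
# item with thresholds tau. All moments can therefore be computed in the
# all-positive parameterization, including for the reversed depressive-mood
# outcome.
attenuation_table <- function(config) {
  inst <- config$instrument
  specs <- config$scale_specs
  moments_for <- function(items, scales) {
    lambda <- numeric(0); tau <- list()
    for (sc in scales) {
      def <- inst$scales[[sc]]
      keep <- def$items %in% items
      if (!any(keep)) next
      lambda <- c(lambda, specs[[sc]]$lambda[keep])
      tau <- c(tau, rep(list(specs[[sc]]$thresholds), sum(keep)))
    }
    p <- length(lambda)
    score_moments(lambda, tau, rep(1, p), rep(1, p))
  }
  out <- list()
  for (nm in names(inst$predictors)) {
    p <- inst$predictors[[nm]]
    out[[nm]] <- moments_for(p$items, p$scales)
  }
  for (nm in names(inst$outcomes)) {
    sc <- inst$outcomes[[nm]]$scale
    m <- moments_for(inst$scales[[sc]]$items, sc)
    m$flip <- 1
    out[[nm]] <- m
  }
  out
}

# generator-side latent correlation matrix after undoing attenuation
compensate_latent_corr <- function(config, atten,
                                   reference_predictor = "cvat2_11item") {
  target <- config$latent_corr
  if (!config$effects_are_observed) return(target)
  gen <- target
  mx <- atten[[reference_predictor]]
  wk <- c(W1 = "general_mental_health", W2 = "absence_depressive_mood",
          W3 = "life_satisfaction")
  for (w in names(wk)) {
    my <- atten[[wk[[w]]]]
    gen["D", w] <- gen[w, "D"] <-
      latent_from_observed(target["D", w], mx, my, flip = my$flip)
  }
  for (i in c("W1", "W2")) for (j in c("W2", "W3")) {
    if (i == j) next
    mi <- atten[[wk[[i]]]]; mj <- atten[[wk[[j]]]]
    gen[i, j] <- gen[j, i] <-
      latent_from_observed(target[i, j], mi, mj, flip = mi$flip * mj$flip)
  }
  ev <- min(eigen(gen, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8)
    stop("attenuation-compensated latent correlation matrix is not positive ",
         "definite; weaken the configured effects or raise loadings",
         call. = FALSE)
  gen
}

# ---- generation --------------------------------------------------------------

#' Generate a synthetic survey dataset with ground truth
#'
#' Draws correlated latent constructs, generates Likert items by factor
#' loadings with threshold discretization, simulates demographics and playtime,
#' then applies page-level dropout, careless (patterned, check-failing)
#' responding and extreme-playtime outliers. Counts of dropouts, careless
#' responders and outliers are deterministic (`round(rate * n)`); which
#' respondents are affected is random under the seed.
#'
#' @param config a [survey_config()].
#' @return list with `data` (tibble, one row per respondent who began the
#'   survey) and `truth` (ground-truth record: per-respondent labels,
#'   generator-side latent correlations, per-score attenuation factors).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  inst <- config$instrument
  cs <- config$covariate_spec
  atten <- attenuation_table(config)
  gen_corr <- compensate_latent_corr(config, atten)

  set.seed(config$seed)
  n <- config$n_respondents

  # membership: dropouts, then careless among completers, then outliers among
  # attentive completers
  n_drop <- round(config$dropout_rate * n)
  n_complete <- n - n_drop
  n_careless <- round(config$careless_rate * n_complete)
  n_outlier <- round(config$outlier_rate * (n_complete - n_careless))
  status <- rep("complete", n)
  ord <- sample.int(n)
  drop_ids <- ord[seq_len(n_drop)]
  careless_ids <- ord[n_drop + seq_len(n_careless)]
  outlier_ids <- ord[n_drop + n_careless + seq_len(n_outlier)]
  status[drop_ids] <- "dropout"
  status[careless_ids] <- "careless"

  # latent constructs
  L <- matrix(rnorm(n * 4), n, 4) %*% chol(gen_corr)
  colnames(L) <- c("D", "W1", "W2", "W3")

  # demographics
  age <- round(cs$age$min + rgamma(n, shape = cs$age$shape, scale = cs$age$scale))
  gender <- sample(cs$gender$levels, n, replace = TRUE, prob = cs$gender$probs)
  education <- sample(cs$education$levels, n, replace = TRUE,
                      prob = cs$education$probs)
  male <- gender == "male"
  for (w in names(cs$gender$male_shift))
    L[, w] <- L[, w] + cs$gender$male_shift[[w]] * male

  # playtime (right-skewed; weakly driven by dysregulation)
  pt <- cs$playtime
  weekly <- rlnorm(n, pt$weekly_meanlog + pt$d_loading * L[, "D"], pt$weekly_sdlog)
  session <- rlnorm(n, cs$session$meanlog + cs$session$d_loading * L[, "D"],
                    cs$session$sdlog)
  # implant outliers: extreme weekly time or session duration, guaranteed to
  # exceed mean + 3 sd of the final playtime distribution
  if (n_outlier > 0) {
    kind <- sample(c("weekly", "session"), n_outlier, replace = TRUE,
                   prob = c(0.7, 0.3))
    k <- 6
    repeat {
      w2 <- weekly; s2 <- session
      w2[outlier_ids[kind == "weekly"]] <-
        mean(weekly) + k * sd(weekly) * runif(sum(kind == "weekly"), 1, 1.4)
      s2[outlier_ids[kind == "session"]] <-
        mean(session) + k * sd(session) * runif(sum(kind == "session"), 1, 1.4)
      hit <- (w2[outlier_ids] >= mean(w2) + 3 * sd(w2)) |
             (s2[outlier_ids] >= mean(s2) + 3 * sd(s2))
      if (all(hit) || k > 50) break
      k <- k * 1.5
    }
    weekly <- w2; session <- s2
  }
  share <- pmin(pmax(pt$weekday_share + rnorm(n, 0, pt$share_noise), 0.2), 0.9)
  weekday_hours <- round(weekly * share / 5, 1)
  weekend_hours <- round(weekly * (1 - share) / 2, 1)
  session_minutes <- round(session)

  # motivation / need-satisfaction scores (direct scale scores on [1, 5])
  wbar <- rowMeans(L[, c("W1", "W2", "W3")])
  likert_cov <- lapply(cs$likert_covariates, function(sp) {
    raw <- sp$d * L[, "D"] + sp$w * wbar +
      rnorm(n, 0, sqrt(max(1 - sp$d^2 - sp$w^2, 0.1)))
    round(pmin(pmax(sp$mean + sp$sd * raw, 1), 5), 2)
  })

  # items
  items <- list()
  for (sc in names(inst$scales)) {
    def <- inst$scales[[sc]]
    sp <- config$scale_specs[[sc]]
    f <- switch(def$construct,
                dysregulation = L[, "D"],
                general_mental_health = L[, "W1"],
                depressive_mood = L[, "W2"],
                life_satisfaction = L[, "W3"])
    dir <- if (identical(def$construct, "depressive_mood")) -1 else 1
    for (j in seq_along(def$items)) {
      # items worded against the scored direction load on -F and use mirrored
      # thresholds, so reverse coding restores the positive-item distribution
      g <- dir * if (def$items[j] %in% def$reverse) -1 else 1
      tau <- if (g < 0) -rev(sp$thresholds) else sp$thresholds
      lam <- sp$lambda[j]
      ystar <- g * lam * f + sqrt(1 - lam^2) * rnorm(n)
      items[[def$items[j]]] <- likert_discretize(ystar, tau)
    }
  }

  # attention checks: attentive respondents pass (1); careless fail >= 1
  check_1 <- rep(1L, n)
  check_2 <- rep(1L, n)
  if (n_careless > 0) {
    which_fail <- sample(c("first", "second", "both"), n_careless,
                         replace = TRUE, prob = c(0.35, 0.35, 0.3))
    check_1[careless_ids[which_fail != "second"]] <- 0L
    check_2[careless_ids[which_fail != "first"]] <- 0L
    # patterned item responses: constant, or repeating 1-2-3
    pattern <- sample(c("1", "2", "3", "4", "5", "123"), n_careless,
                      replace = TRUE)
    item_names <- unlist(lapply(inst$scales, `[[`, "items"))
    for (i in seq_len(n_careless)) {
      id <- careless_ids[i]
      vals <- if (pattern[i] == "123") {
        rep_len(c(1L, 2L, 3L), length(item_names))
      } else rep(as.integer(pattern[i]), length(item_names))
      for (j in seq_along(item_names)) items[[item_names[j]]][id] <- vals[j]
      for (v in names(likert_cov))
        likert_cov[[v]][id] <- if (pattern[i] == "123") 2 else as.numeric(pattern[i])
    }
  } else {
    pattern <- character(0)
  }

  data <- tibble::tibble(
    id = sprintf("r%04d", seq_len(n)),
    age = age, gender = gender, education = education,
    weekday_hours = weekday_hours, weekend_hours = weekend_hours,
    session_minutes = session_minutes
  )
  for (v in names(likert_cov)) data[[v]] <- likert_cov[[v]]
  for (it in names(items)) data[[it]] <- items[[it]]
  data$check_1 <- check_1
  data$check_2 <- check_2

  # page-level dropout: everything from the abandonment page onward is missing
  dropout_page <- rep(NA_integer_, n)
  if (n_drop > 0) {
    pages <- inst$pages
    # heavy early abandonment (most dropouts within the first three measures)
    wts <- c(10, 32, 30, 25, rep(3, max(length(pages) - 4, 0)))[seq_along(pages)]
    dropout_page[drop_ids] <- sample(seq_along(pages), n_drop, replace = TRUE,
                                     prob = wts)
    page_cols <- page_columns(inst)
    for (id in drop_ids) {
      gone <- unlist(page_cols[dropout_page[id]:length(pages)])
      data[id, gone] <- NA
    }
  }

  truth <- list(
    labels = tibble::tibble(
      id = data$id, status = status,
      careless = status == "careless",
      dropout = status == "dropout",
      dropout_page = dropout_page,
      careless_pattern = {
        cp <- rep(NA_character_, n); cp[careless_ids] <- pattern; cp
      },
      outlier = data$id %in% data$id[outlier_ids]
    ),
    target_corr = config$latent_corr,
    generator_corr = gen_corr,
    effects_are_observed = config$effects_are_observed,
    attenuation = vapply(atten, function(m) m$attenuation, numeric(1)),
    reference_predictor = "cvat2_11item",
    counts = c(n = n, dropout = n_drop, careless = n_careless,
               outlier = n_outlier),
    seed = config$seed
  )
  list(data = data, truth = truth)
}

# map survey pages to the columns they contain
page_columns <- function(inst) {
  cols <- list(
    demographics = c("age", "gender", "education", "weekday_hours",
                     "weekend_hours", "session_minutes"),
    motivations = paste0("mot_", c("habit", "narrative", "pastime",
                                   "performance", "reactivity", "social",
                                   "escapism", "agency")),
    needs = paste0("need_", c("autonomy", "competence", "relatedness"))
  )
  for (sc in names(inst$scales)) cols[[sc]] <- inst$scales[[sc]]$items
  for (chk in names(inst$checks))
    cols[[inst$checks[[chk]]]] <- c(cols[[inst$checks[[chk]]]], chk)
  cols[inst$pages]
}

#' Write / read a synthetic survey
#'
#' The respondent table is written as plain CSV (header row; missing items
#' empty), the ground-truth record as JSON.
#'
#' @param survey result of [generate_survey()].
#' @param data_path CSV path for the respondent table.
#' @param truth_path optional JSON path for the ground truth.
#' @return `data_path`, invisibly.
#' @export
write_survey <- function(survey, data_path, truth_path = NULL) {
  write.csv(survey$data, data_path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    tr <- survey$truth
    tr$target_corr <- as.data.frame(tr$target_corr)
    tr$generator_corr <- as.data.frame(tr$generator_corr)
    tr$attenuation <- as.list(tr$attenuation)
    tr$counts <- as.list(tr$counts)
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "columns")
  }
  invisible(data_path)
}

#' @rdname write_survey
#' @param path CSV path to read.
#' @export
read_survey <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  tibble::as_tibble(raw)
}
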