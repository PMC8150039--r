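#' Clean a raw survey dataset
#'
#' Applies the cleaning cascade: respondents with any missing item or
#' attention-check value ("incomplete") are removed first, then completers who
#' failed one or both attention checks ("careless"). In sensitivity mode the
#' cascade is disabled and everyone is retained (incomplete respondents keep
#' their missing values and drop out of individual analyses listwise).
#'
#' @param raw respondent table (tibble) containing item columns, `check_1` /
#'   `check_2` attention-check columns (1 = pass, 0 = fail) and demographics.
#' @param sensitivity_mode logical; retain incomplete and careless respondents.
#' @param item_cols character vector of item column names; defaults to every
#'   column of the packaged instrument present in `raw`.
#' @return list with `data` (cleaned tibble) and `report` (a `cleaning_report`:
#'   `n_initial = n_incomplete_removed + n_careless_removed + n_retained`).
#' @export
clean_dataset <- function(raw, sensitivity_mode = FALSE, item_cols = NULL) {
  check_cols <- c("check_1", "check_2")
  if (!all(check_cols %in% names(raw)))
    stop("attention-check columns check_1 / check_2 are missing", call. = FALSE)
  if (is.null(item_cols)) {
    inst <- load_instrument()
    item_cols <- intersect(unlist(lapply(inst$scales, `[[`, "items")),
                           names(raw))
  }
  if (length(item_cols) == 0) stop("no item columns found", call. = FALSE)

  n_initial <- nrow(raw)
  if (sensitivity_mode) {
    report <- cleaning_report(n_initial, 0L, 0L, n_initial,
                              sensitivity_mode = TRUE)
    return(list(data = raw, report = report))
  }
  focal <- raw[, c(item_cols, check_cols)]
  complete <- complete.cases(focal)
  completers <- raw[complete, , drop = FALSE]
  pass <- completers$check_1 == 1L & completers$check_2 == 1L
  retained <- completers[pass, , drop = FALSE]
  report <- cleaning_report(
    n_initial,
    n_incomplete_removed = sum(!complete),
    n_careless_removed = sum(!pass),
    n_retained = nrow(retained),
    sensitivity_mode = FALSE,
    removed_careless_ids = completers$id[!pass]
  )
  list(data = retained, report = report)
}

cleaning_report <- function(n_initial, n_incomplete_removed, n_careless_removed,
                            n_retained, sensitivity_mode,
                            removed_careless_ids = character()) {
  stopifnot(n_initial == n_incomplete_removed + n_careless_removed + n_retained)
  structure(
    list(n_initial = n_initial,
         n_incomplete_removed = n_incomplete_removed,
         n_careless_removed = n_careless_removed,
         n_retained = n_retained,
         pct_incomplete = 100 * n_incomplete_removed / n_initial,
         pct_careless_of_completers =
           100 * n_careless_removed / max(n_initial - n_incomplete_removed, 1),
         sensitivity_mode = sensitivity_mode,
         removed_careless_ids = removed_careless_ids),
    class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %d began; removed %d incomplete (%.1f%%), %d careless (%.1f%% of completers); retained %d%s\n",
    x$n_initial, x$n_incomplete_removed, x$pct_incomplete,
    x$n_careless_removed, x$pct_careless_of_completers, x$n_retained,
    if (x$sensitivity_mode) " [sensitivity mode]" else ""))
  invisible(x)
}

#' Score a scale by its (reverse-coded) item mean
#'
#' Reverse-coded items contribute `6 - response`; the score is the arithmetic
#' mean over the scale's items (or its core subset).
#'
#' @param dataset cleaned respondent table.
#' @param scale a [scale_definition()].
#' @param core_only use only the core-criterion items?
#' @param items optional explicit item subset (overrides `core_only`).
#' @param allow_missing if `TRUE`, respondents with missing items get `NA`
#'   instead of an error (used in sensitivity mode).
#' @return numeric vector of per-respondent scores in `[1, 5]` (or `NA`).
#' @export
score_scale <- function(dataset, scale, core_only = FALSE, items = NULL,
                        allow_missing = FALSE) {
  sel <- items %||% if (core_only) scale$core else scale$items
  missing_cols <- setdiff(sel, names(dataset))
  if (length(missing_cols))
    stop("item columns absent from dataset: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- as.matrix(dataset[, sel, drop = FALSE])
  if (anyNA(m) && !allow_missing)
    stop("missing item values; clean the dataset first or set allow_missing",
         call. = FALSE)
  rev <- sel %in% scale$reverse
  m[, rev] <- 6 - m[, rev, drop = FALSE]
  scores <- rowMeans(m)               # NA rows propagate when allow_missing
  scores
}

#' Weekly game time from weekday/weekend hours
#'
#' `5 * weekday + 2 * weekend` hours per week.
#'
#' @param weekday_hours,weekend_hours non-negative hours per day.
#' @return hours per week.
#' @export
weekly_game_time <- function(weekday_hours, weekend_hours) {
  if (any(weekday_hours < 0, na.rm = TRUE) ||
      any(weekend_hours < 0, na.rm = TRUE))
    stop("play hours must be non-negative", call. = FALSE)
  5 * weekday_hours + 2 * weekend_hours
}

#' Reverse a well-being score
#'
#' Maps a 1-5 mean score onto its mirror image `6 - score`; used to convert
#' depressive mood into absence of depressive mood. The reversal is an
#' involution.
#'
#' @param score numeric score(s) in `[1, 5]`.
#' @return `6 - score`.
#' @export
reverse_wellbeing <- function(score) {
  if (any(score < 1 | score > 5, na.rm = TRUE))
    stop("scores must lie in [1, 5]", call. = FALSE)
  6 - score
}

#' Flag probable playtime outliers
#'
#' Flags respondents whose weekly game time or average session duration lies
#' three or more sample standard deviations above the respective mean, plus
#' respondents reporting a weekly game time of zero hours. Means and SDs are
#' computed over the rows of `scored` (the cleaned sample, before outlier
#' removal). A zero SD disables the corresponding rule.
#'
#' @param scored scored respondent table with `weekly_hours` and
#'   `session_minutes` columns.
#' @return character vector of flagged respondent ids.
#' @export
flag_outliers <- function(scored) {
  stopifnot(all(c("id", "weekly_hours", "session_minutes") %in% names(scored)))
  w <- scored$weekly_hours
  s <- scored$session_minutes
  flag <- rep(FALSE, nrow(scored))
  if (isTRUE(sd(w, na.rm = TRUE) > 0))
    flag <- flag | (w >= mean(w, na.rm = TRUE) + 3 * sd(w, na.rm = TRUE))
  if (isTRUE(sd(s, na.rm = TRUE) > 0))
    flag <- flag | (s >= mean(s, na.rm = TRUE) + 3 * sd(s, na.rm = TRUE))
  flag <- flag | (w == 0)
  scored$id[which(flag)]      # NA (incomplete in sensitivity mode): not flagged
}

#' Score every analysis variable
#'
#' Builds the scored analysis table from a cleaned survey: the nine
#' dysregulated-gaming operationalizations, the three well-being outcomes
#' (depressive mood reversed into absence of depressive mood), weekly game
#' time, and pass-through demographics, motivations, need satisfactions and
#' the item columns used by item-level curves. Adds an `outlier` flag column
#' from [flag_outliers()].
#'
#' @param cleaned cleaned respondent table.
#' @param instrument instrument definition from [load_instrument()].
#' @param allow_missing tolerate missing items (sensitivity mode)?
#' @return scored tibble, one row per respondent.
#' @export
score_dataset <- function(cleaned, instrument = load_instrument(),
                          allow_missing = FALSE) {
  out <- tibble::tibble(id = cleaned$id)
  demo <- c("age", "gender", "education", "weekday_hours", "weekend_hours",
            "session_minutes")
  for (v in demo) out[[v]] <- cleaned[[v]]
  out$gender <- factor(out$gender, levels = c("female", "male", "other"))
  out$education <- factor(out$education, levels = c("tertiary", "secondary"))
  out$weekly_hours <- weekly_game_time(cleaned$weekday_hours,
                                       cleaned$weekend_hours)

  for (v in grep("^(mot|need)_", names(cleaned), value = TRUE))
    out[[v]] <- cleaned[[v]]

  for (nm in names(instrument$predictors)) {
    p <- instrument$predictors[[nm]]
    # synthesize a scale definition over the predictor's item subset
    sdef <- scale_definition(nm, items = p$items, reverse = p$reverse)
    out[[nm]] <- score_scale(cleaned, sdef, allow_missing = allow_missing)
  }
  for (nm in names(instrument$outcomes)) {
    o <- instrument$outcomes[[nm]]
    sc <- instrument$scales[[o$scale]]
    score <- score_scale(cleaned, sc, allow_missing = allow_missing)
    out[[nm]] <- if (isTRUE(o$reversed)) reverse_wellbeing(score) else score
  }
  # retain single items for item-level specification curves
  item_cols <- intersect(unlist(lapply(instrument$scales, `[[`, "items")),
                         names(cleaned))
  clash <- intersect(item_cols, names(out))
  if (length(clash))
    stop("item ids collide with score columns: ",
         paste(clash, collapse = ", "), call. = FALSE)
  for (it in item_cols) out[[it]] <- cleaned[[it]]

  out$outlier <- out$id %in% flag_outliers(out)
  out
}
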