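#' Scale definitions
#'
#' A `scale_definition` names the ordered item ids of a survey scale, which of
#' them are reverse-coded (contributing `6 - response` to the mean score) and
#' which form the "core" (interference / negative-consequence) subset used by
#' core-criteria operationalizations.
#'
#' @param name scale name.
#' @param items character vector of item column ids (at least one).
#' @param reverse character vector of reverse-coded item ids (subset of `items`).
#' @param core character vector of core-criterion item ids (subset of `items`).
#' @param construct label of the latent construct the scale measures.
#' @return An object of class `scale_definition`.
#' @export
scale_definition <- function(name, items, reverse = character(), core = items,
                             construct = name) {
  stopifnot(is.character(items), length(items) >= 1L, !anyDuplicated(items))
  if (!all(reverse %in% items))
    stop("reverse-coded ids must be a subset of the scale's items", call. = FALSE)
  if (!all(core %in% items))
    stop("core ids must be a subset of the scale's items", call. = FALSE)
  structure(
    list(name = name, items = items, reverse = reverse, core = core,
         construct = construct),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat("<scale_definition> ", x$name, " (", x$construct, "): ",
      length(x$items), " items, ", length(x$reverse), " reverse-coded, ",
      length(x$core), " core\n", sep = "")
  invisible(x)
}

#' Load the survey instrument definition
#'
#' Reads a YAML instrument config (scales with item / reverse / core sets, page
#' order, attention-check placement, predictor operationalizations, outcome
#' scales). The packaged default emulates a gamer survey with five
#' dysregulated-gaming instruments (nine scale operationalizations) and three
#' well-being measures.
#'
#' @param path path to a YAML instrument file; default is the packaged one.
#' @return A list with elements `scales` (named list of [scale_definition()]),
#'   `pages`, `checks`, `predictors`, `outcomes`.
#' @export
load_instrument <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "scales.yaml", package = "specwell",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  scales <- lapply(names(raw$scales), function(nm) {
    s <- raw$scales[[nm]]
    scale_definition(nm, items = unlist(s$items),
                     reverse = as.character(unlist(s$reverse)),
                     core = as.character(unlist(s$core)),
                     construct = s$construct %||% nm)
  })
  names(scales) <- names(raw$scales)

  predictors <- lapply(raw$predictors, function(p) {
    sc <- unlist(p$scale)
    items <- unlist(lapply(sc, function(s) scales[[s]]$items))
    sub <- p$subset
    if (identical(sub, "all")) {
      sel <- items
    } else if (identical(sub, "core")) {
      stopifnot(length(sc) == 1L)
      sel <- scales[[sc]]$core
    } else {
      sel <- as.character(unlist(sub))
    }
    reverse <- unlist(lapply(sc, function(s) scales[[s]]$reverse))
    list(scales = sc, items = sel, reverse = intersect(reverse, sel))
  })

  list(
    scales = scales,
    pages = unlist(raw$pages),
    checks = raw$attention_checks,
    predictors = predictors,
    outcomes = raw$outcomes
  )
}

#' Names of the default specification-space axes
#'
#' The 16 candidate control variables: three demographics, two play-intensity
#' measures, three in-game need satisfactions and eight gaming motivations.
#' @return character vector of covariate column names.
#' @export
default_covariates <- function() {
  c("age", "gender", "education", "weekly_hours", "session_minutes",
    "need_autonomy", "need_competence", "need_relatedness",
    "mot_habit", "mot_narrative", "mot_pastime", "mot_performance",
    "mot_reactivity", "mot_social", "mot_escapism", "mot_agency")
}

#' @rdname default_covariates
#' @export
default_outcomes <- function() {
  c("general_mental_health", "absence_depressive_mood", "life_satisfaction")
}

#' @rdname default_covariates
#' @export
default_predictors <- function() {
  c("vat", "vat_core", "cvat2_9item", "cvat2_11item", "cvat2_core",
    "icd11", "odba", "gko", "cvat3")
}
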