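#' Pipeline configuration
#'
#' @param data path to a respondent CSV, or `NULL` to simulate.
#' @param sim_config a [survey_config()] used when `data` is `NULL`; its seed
#'   is re-derived from `seed` so the whole run is governed by one seed.
#' @param sensitivity_mode retain incomplete and careless respondents?
#' @param item_level also run the single-item specification curve?
#' @param figures write figures?
#' @param covariate_stats collect per-covariate statistics?
#' @param psychometrics run the CFA/omega stage (`"full"` with bootstrap CIs,
#'   `"point"` without, `"off"`)?
#' @param drop_predictor predictor whose removal is probed in the second
#'   variance decomposition (`NULL` to skip).
#' @param seed master integer seed.
#' @param out_dir output directory (created if missing).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(data = NULL, sim_config = NULL,
                            sensitivity_mode = FALSE, item_level = FALSE,
                            figures = TRUE, covariate_stats = TRUE,
                            psychometrics = c("full", "point", "off"),
                            drop_predictor = "odba",
                            seed = 1L, out_dir = tempfile("specwell_run_")) {
  structure(list(data = data, sim_config = sim_config,
                 sensitivity_mode = isTRUE(sensitivity_mode),
                 item_level = isTRUE(item_level), figures = isTRUE(figures),
                 covariate_stats = isTRUE(covariate_stats),
                 psychometrics = match.arg(psychometrics),
                 drop_predictor = drop_predictor,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()] (`seed`,
#' `out_dir`, `data`, `sensitivity_mode`, `item_level`, `figures`,
#' `covariate_stats`, `psychometrics`, `drop_predictor`); an optional
#' `simulate` block carries [survey_config()] arguments (`n_respondents`,
#' `dropout_rate`, `careless_rate`, `outlier_rate`, `d_effects`,
#' `effects_are_observed`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulate)) {
    s <- raw$simulate
    args <- s[intersect(names(s), c("n_respondents", "dropout_rate",
                                    "careless_rate", "outlier_rate",
                                    "effects_are_observed"))]
    if (!is.null(s$d_effects))
      args$latent_corr <- default_latent_corr(unlist(s$d_effects))
    sim <- do.call(survey_config, args)
  }
  keep <- intersect(names(raw), c("data", "sensitivity_mode", "item_level",
                                  "figures", "covariate_stats",
                                  "psychometrics", "drop_predictor", "seed",
                                  "out_dir"))
  do.call(pipeline_config, c(raw[keep], list(sim_config = sim)))
}

#' Run the full analysis pipeline
#'
#' simulate/ingest -> clean -> score -> psychometrics -> specification curve
#' -> summaries -> variance decomposition -> figures, writing CSV/JSON (and
#' PNG) outputs plus a run manifest into `config$out_dir`. A stage failure
#' aborts the run and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly; all artefacts are on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  created <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) {
    if (created) unlink(out, recursive = TRUE) else
      unlink(list.files(out, full.names = TRUE))
  })

  inst <- load_instrument()
  manifest <- list(seed = config$seed,
                   sensitivity_mode = config$sensitivity_mode,
                   item_level = config$item_level,
                   package_version = as.character(utils::packageVersion("specwell")),
                   stages = list())

  # -- ingest / simulate
  if (is.null(config$data)) {
    sim <- config$sim_config %||% survey_config()
    sim$seed <- derive_seed(config$seed, "simulate")
    survey <- generate_survey(sim)
    raw <- survey$data
    write_survey(survey, file.path(out, "survey.csv"),
                 file.path(out, "ground_truth.json"))
    manifest$stages$simulate <- list(n = nrow(raw),
                                     seed = sim$seed)
  } else {
    raw <- read_survey(config$data)
    manifest$stages$ingest <- list(n = nrow(raw), path = config$data)
  }

  # -- clean
  cleaned <- clean_dataset(raw, sensitivity_mode = config$sensitivity_mode)
  jsonlite::write_json(unclass(cleaned$report)[1:7],
                       file.path(out, "cleaning_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$stages$clean <- unclass(cleaned$report)[1:4]

  # -- score
  scored <- score_dataset(cleaned$data, inst,
                          allow_missing = config$sensitivity_mode)
  write.csv(scored, file.path(out, "scored.csv"), row.names = FALSE, na = "")
  manifest$stages$score <- list(n = nrow(scored),
                                n_outliers = sum(scored$outlier))

  # -- psychometrics
  if (config$psychometrics != "off") {
    sets <- instrument_item_sets(inst)
    psych <- psychometric_report(
      scored[!scored$outlier, ], sets,
      seed = derive_seed(config$seed, "omega"),
      omega_ci = config$psychometrics == "full")
    write.csv(psych, file.path(out, "psychometrics.csv"), row.names = FALSE)
    manifest$stages$psychometrics <- list(n_scales = nrow(psych))
  }

  # -- specification curve
  space <- build_default_space(scored, instrument = inst)
  results <- run_curve(scored, space, covariate_stats = config$covariate_stats)
  flat <- dplyr::select(results, -"coefs")
  write.csv(flat, file.path(out, "curve_results.csv"), row.names = FALSE)
  summary_tab <- summarize_curve_table(results, space)
  write.csv(summary_tab, file.path(out, "curve_summary.csv"), row.names = FALSE)
  overall <- summarize_curve(results)
  write.csv(overall, file.path(out, "curve_overall.csv"), row.names = FALSE)
  manifest$stages$curve <- list(n_specifications = nrow(results),
                                n_degenerate = sum(results$degenerate),
                                median_beta = overall$median_beta)

  write.csv(as.data.frame(correlation_matrix(scored)),
            file.path(out, "correlation_matrix.csv"))

  # -- variance decomposition
  vc <- decompose_variance(results)
  vc_red <- NULL
  if (!is.null(config$drop_predictor)) {
    vc_red <- rerun_without_predictor(results, config$drop_predictor)
    vc_out <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(vc), run = "full"),
      dplyr::mutate(tibble::as_tibble(vc_red),
                    run = paste0("without_", config$drop_predictor)))
  } else vc_out <- dplyr::mutate(tibble::as_tibble(vc), run = "full")
  write.csv(vc_out, file.path(out, "variance_decomposition.csv"),
            row.names = FALSE)
  manifest$stages$decompose <- list(method = attr(vc, "method"),
                                    shares = setNames(vc$share, vc$class))

  # -- item-level curve
  if (config$item_level) {
    ispace <- build_default_space(scored, item_level = TRUE, instrument = inst)
    iresults <- run_curve(scored, ispace, covariate_stats = FALSE)
    write.csv(dplyr::select(iresults, -"coefs"),
              file.path(out, "item_curve_results.csv"), row.names = FALSE)
    isum <- summarize_curve_table(iresults, ispace)
    write.csv(isum[order(isum$median_beta), ],
              file.path(out, "item_curve_summary.csv"), row.names = FALSE)
    manifest$stages$item_curve <- list(n_specifications = nrow(iresults))
  }

  # -- figures
  if (config$figures) {
    plot_specification_curve(results, file.path(out, "specification_curve"))
    plot_choice_boxplots(results, file.path(out, "choice_boxplots"))
    plot_variance_shares(vc, vc_red, path = file.path(out, "variance_shares"))
    manifest$stages$figures <- list(written = 3L)
  }

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  manifest$config_hash <- rlang::hash(cfg_for_hash)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
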