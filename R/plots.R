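#' Plotting data for a specification curve
#'
#' Orders results ascending by effect size (ties broken by enumeration index)
#' and builds the decision-panel bookkeeping: one row per decision level with
#' the x-positions of the specifications adopting it.
#'
#' @param results tibble from [run_curve()].
#' @return list with `ordered` (results plus `position`) and `panel` (long
#'   tibble: `class`, `level`, `position`).
#' @export
curve_plot_data <- function(results) {
  results <- results[!results$degenerate, , drop = FALSE]
  if (!nrow(results)) stop("no results to plot", call. = FALSE)
  ord <- results[order(results$beta, results$spec_id), , drop = FALSE]
  ord$position <- seq_len(nrow(ord))
  classes <- c(outcome = "outcome", predictor = "predictor",
               covariates = "covariate_set", subset = "outlier_choice")
  panel <- dplyr::bind_rows(lapply(names(classes), function(cl) {
    tibble::tibble(class = cl, level = as.character(ord[[classes[[cl]]]]),
                   position = ord$position)
  }))
  panel$class <- factor(panel$class, levels = names(classes))
  list(ordered = ord, panel = panel)
}

#' Specification curve figure
#'
#' Top panel: per-specification standardized coefficients with 95% CI bars,
#' sorted ascending, dashed line at the curve median. Bottom panel: one row
#' per decision level with a tick aligned under each specification adopting
#' that level.
#'
#' @param results tibble from [run_curve()].
#' @param path optional output path without extension; written via
#'   [save_figure()] in the requested formats.
#' @param formats any of `"png"`, `"svg"`.
#' @return the patchwork plot object, invisibly if written to file.
#' @export
plot_specification_curve <- function(results, path = NULL, formats = "png") {
  pd <- curve_plot_data(results)
  med <- median(pd$ordered$beta)
  top <- ggplot2::ggplot(pd$ordered, ggplot2::aes(x = .data$position,
                                                  y = .data$beta)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ci_lo,
                                         ymax = .data$ci_hi),
                            colour = "#f4a6a0", linewidth = 0.3) +
    ggplot2::geom_point(colour = "#8b1a1a", size = 0.5) +
    ggplot2::geom_hline(yintercept = med, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "standardized β") +
    ggplot2::theme_minimal()
  bottom <- ggplot2::ggplot(pd$panel,
                            ggplot2::aes(x = .data$position, y = .data$level)) +
    ggplot2::geom_point(shape = "|", size = 2, colour = "#8b1a1a") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$class), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "specifications (ordered by effect size)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
  plt <- patchwork::wrap_plots(top, bottom, ncol = 1, heights = c(1, 2))
  if (!is.null(path)) {
    save_figure(plt, path, formats, width = 9, height = 10)
    return(invisible(plt))
  }
  plt
}

#' Box plots of effect sizes per decision level
#'
#' One box per decision level over the coefficients of all models adopting
#' that level; the box's centre line is the level's median, fliers (standard
#' 1.5 x IQR whiskers) are marked in red.
#'
#' @inheritParams plot_specification_curve
#' @return the ggplot object, invisibly if written to file.
#' @export
plot_choice_boxplots <- function(results, path = NULL, formats = "png") {
  pd <- curve_plot_data(results)
  plt <- ggplot2::ggplot(pd$panel,
                         ggplot2::aes(x = pd$ordered$beta[.data$position],
                                      y = .data$level)) +
    ggplot2::geom_boxplot(outlier.colour = "red", outlier.size = 0.8,
                          linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$class), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "standardized β", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    save_figure(plt, path, formats, width = 7, height = 9)
    return(invisible(plt))
  }
  plt
}

#' Bar chart of decomposed variance shares
#'
#' @param vc a `variance_components` tibble from [decompose_variance()].
#' @param vc_reduced optional second decomposition (e.g. with an anomalous
#'   predictor removed) drawn alongside.
#' @inheritParams plot_specification_curve
#' @return the ggplot object, invisibly if written to file.
#' @export
plot_variance_shares <- function(vc, vc_reduced = NULL, path = NULL,
                                 formats = "png") {
  d <- tibble::tibble(class = vc$class, share = vc$share, run = "full curve")
  if (!is.null(vc_reduced))
    d <- dplyr::bind_rows(d, tibble::tibble(class = vc_reduced$class,
                                            share = vc_reduced$share,
                                            run = "reduced curve"))
  plt <- ggplot2::ggplot(d, ggplot2::aes(x = .data$class,
                                         y = 100 * .data$share,
                                         fill = .data$run)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("#6a51a3", "#238b45")) +
    ggplot2::labs(x = "decision class", y = "% of effect-size variance",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    save_figure(plt, path, formats, width = 6, height = 4)
    return(invisible(plt))
  }
  plt
}

#' Write a plot as PNG and/or SVG
#'
#' @param plt a ggplot/patchwork object.
#' @param path output path without extension.
#' @param formats any of `"png"`, `"svg"`.
#' @param width,height size in inches.
#' @return paths written, invisibly.
#' @export
save_figure <- function(plt, path, formats = c("png", "svg"),
                        width = 7, height = 5) {
  written <- character(0)
  for (fmt in match.arg(formats, c("png", "svg"), several.ok = TRUE)) {
    f <- paste0(path, ".", fmt)
    if (fmt == "png") {
      ggplot2::ggsave(f, plt, width = width, height = height, dpi = 150)
    } else {
      grDevices::svg(f, width = width, height = height)
      print(plt)
      grDevices::dev.off()
    }
    written <- c(written, f)
  }
  invisible(written)
}
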