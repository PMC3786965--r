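#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Discriminant-score scatterplot
#'
#' Scores on the first two canonical functions, coloured by group, with the
#' percent of between-group variance and the Wilks p-value on the axis
#' labels — the standard way of displaying how treatment groups separate.
#' Falls back to a one-dimensional strip when the fit has a single
#' function.
#'
#' @param object A `cda_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cda_fit
#' @export
autoplot.cda_fit <- function(object, ...) {
  sc <- da_scores(object)
  fns <- object$functions
  lab <- function(i) sprintf("Function %d (%.1f%%; p = %.3g)", i,
                             fns$pct_variance[i], fns$p_value[i])
  if (ncol(object$scores) >= 2) {
    ggplot2::ggplot(sc, ggplot2::aes(
      x = .data$Function1, y = .data$Function2,
      colour = .data[[object$grouping]])) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(x = lab(1), y = lab(2), colour = object$grouping) +
      ggplot2::theme_bw()
  } else {
    ggplot2::ggplot(sc, ggplot2::aes(
      x = .data[[object$grouping]], y = .data$Function1,
      colour = .data[[object$grouping]])) +
      ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
      ggplot2::labs(y = lab(1), x = object$grouping) +
      ggplot2::theme_bw() +
      ggplot2::theme(legend.position = "none")
  }
}

#' Group-mean bar chart with standard errors
#'
#' Mean +1 SEM of a derived measure per treatment group, split by strain —
#' the display convention used for composite behaviour scores.
#'
#' @param data Data frame of per-animal measures (e.g.
#'   [derived_measures()] output) with `group` and `strain` columns.
#' @param measure Name of the measure column.
#' @return A ggplot object.
#' @export
plot_group_means <- function(data, measure) {
  data <- as_tibble(data)
  stopifnot(measure %in% names(data),
            all(c("group", "strain") %in% names(data)))
  summ <- data |>
    dplyr::group_by(.data$group, .data$strain) |>
    dplyr::summarise(
      mean = mean(.data[[measure]], na.rm = TRUE),
      sem = stats::sd(.data[[measure]], na.rm = TRUE) /
        sqrt(sum(!is.na(.data[[measure]]))),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = base::factor(.data$group, levels = GROUP_LABELS))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$strain)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = "treatment group", y = measure, fill = "strain") +
    ggplot2::theme_bw()
}

#' Render the report figures
#'
#' One discriminant scatterplot per analysis arm (treatment-grouping DA)
#' and one group-mean bar chart per derived measure. Purely presentational;
#' a missing table skips its figure with a warning.
#'
#' @param report A `pain_report` from [run_pipeline()].
#' @param dir Output directory; `NULL` returns the plot list without
#'   writing files.
#' @param device File extension for saved figures (default `"png"`).
#' @return Named list of ggplot objects, invisibly when written.
#' @export
make_figures <- function(report, dir = NULL, device = "png") {
  stopifnot(inherits(report, "pain_report"))
  plots <- list()
  if (length(report$arms) == 0) {
    warn("empty report: no figures to draw")
    return(plots)
  }
  for (a in names(report$arms)) {
    res <- report$arms[[a]]
    plots[[paste0(a, "_da2_scatter")]] <- autoplot(res$da2)
    for (v in res$da2_vars) {
      if (!v %in% names(res$measures)) {
        warn(sprintf("measure '%s' missing from %s arm; skipping figure", v, a))
        next
      }
      plots[[paste0(a, "_", v)]] <- plot_group_means(res$measures, v)
    }
  }
  if (!is.null(report$weight)) {
    plots$weight_pct_change <- plot_group_means(report$weight,
                                                "weight_pct_change")
  }
  if (!is.null(report$cort)) {
    plots$cort_log_change <- plot_group_means(report$cort, "cort_log_change")
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(dir, paste0(nm, ".", device)), plots[[nm]],
                      width = 7, height = 5, dpi = 150)
    }
    return(invisible(plots))
  }
  plots
}
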