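#' Plot methods
#'
#' Quick ggplot2 views of the three result types: normalised adequacy
#' scores per nutrient (0 marks the recommended level; limit-type
#' nutrients pass below 0), stacked food-group contributions per footprint
#' indicator, and daily cost with interquartile error bars.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plantshift-plots
NULL

#' @rdname plantshift-plots
#' @method autoplot adequacy_report
#' @export
autoplot.adequacy_report <- function(object, ...) {
  dat <- strip_class(object) |> filter(!is.na(.data$score))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$nutrient, y = .data$score,
                                    fill = .data$meets)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e7d32",
                                          `FALSE` = "#c62828")) +
    ggplot2::labs(y = "normalised deviation from recommendation",
                  x = NULL, fill = "meets")
}

#' @rdname plantshift-plots
#' @method autoplot impact_result
#' @export
autoplot.impact_result <- function(object, ...) {
  dat <- strip_class(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$scenario,
                                    y = .data$contribution,
                                    fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$indicator), scales = "free_y") +
    ggplot2::labs(y = "impact per person per day", x = NULL,
                  fill = "food group") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname plantshift-plots
#' @method autoplot expenditure_report
#' @export
autoplot.expenditure_report <- function(object, ...) {
  dat <- strip_class(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$scenario, y = .data$median)) +
    ggplot2::geom_col(fill = "#546e7a") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                           width = 0.3) +
    ggplot2::labs(y = sprintf("daily food expenditure (%s/day)",
                              dat$currency[1]),
                  x = NULL)
}
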