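#' Tidiers for result objects
#'
#' `tidy()` returns the underlying long tibble without the result class;
#' `glance()` condenses a result to one row per scenario (and basis).
#'
#' @param x A result object (`adequacy_report`, `impact_report`,
#'   `impact_result`, `expenditure_report` or `expenditure_result`).
#' @param ... Unused.
#' @return A tibble.
#' @name plantshift-tidiers
NULL

strip_class <- function(x) {
  out <- as_tibble(x)
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname plantshift-tidiers
#' @method tidy adequacy_report
#' @export
tidy.adequacy_report <- function(x, ...) strip_class(x)

#' @rdname plantshift-tidiers
#' @method tidy impact_report
#' @export
tidy.impact_report <- function(x, ...) strip_class(x)

#' @rdname plantshift-tidiers
#' @method tidy impact_result
#' @export
tidy.impact_result <- function(x, ...) strip_class(x)

#' @rdname plantshift-tidiers
#' @method tidy expenditure_report
#' @export
tidy.expenditure_report <- function(x, ...) strip_class(x)

#' @rdname plantshift-tidiers
#' @method tidy expenditure_result
#' @export
tidy.expenditure_result <- function(x, ...) strip_class(x)

#' @rdname plantshift-tidiers
#' @method glance adequacy_report
#' @export
glance.adequacy_report <- function(x, ...) {
  strip_class(x) |>
    group_by(across(any_of(c("scenario", "basis")))) |>
    summarise(
      n_nutrients = sum(!is.na(.data$meets)),
      n_met = sum(.data$meets, na.rm = TRUE),
      prop_met = .data$n_met / .data$n_nutrients,
      .groups = "drop"
    )
}

#' @rdname plantshift-tidiers
#' @method glance impact_report
#' @export
glance.impact_report <- function(x, ...) {
  strip_class(x) |>
    tidyr::pivot_wider(id_cols = any_of(c("scenario", "basis")),
                       names_from = "indicator",
                       values_from = c("total", "pct_change_vs_bau"))
}

#' @rdname plantshift-tidiers
#' @method glance expenditure_report
#' @export
glance.expenditure_report <- function(x, ...) strip_class(x)
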