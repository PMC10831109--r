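#' Nutrient supply of a diet
#'
#' Per-day nutrient amounts: `supply = sum over items of amount_kg x
#' content per kg` at the chosen quantile of the composition data.
#' Fortified nutrients enter through the item content like any other.
#' Group-level rows are split across items (see [allocate_items()]).
#'
#' @param diet A diet-profile tibble (one or more scenarios).
#' @param db A [food_db()].
#' @param quantile `"median"`, `"q25"` or `"q75"` composition values.
#' @return Tibble: `scenario` (and `basis` if present), `nutrient`, `unit`,
#'   `supply` (amount/day). An empty diet yields zero for every nutrient in
#'   the database.
#' @export
nutrient_supply <- function(diet, db, quantile = c("median", "q25", "q75")) {
  quantile <- match.arg(quantile)
  stopifnot(inherits(db, "food_db"))
  items <- allocate_items(diet, db)
  nutrients <- pick_quantile(db$nutrients, quantile)
  nutrient_set <- distinct(db$nutrients, .data$nutrient, .data$unit)

  used <- unique(items$item_id)
  coverage <- tidyr::expand_grid(item_id = used,
                                 nutrient = nutrient_set$nutrient) |>
    anti_join(nutrients, by = c("item_id", "nutrient"))
  if (nrow(coverage) > 0) {
    abort(sprintf(
      "composition table lacks nutrient(s) %s for item(s) %s",
      paste(unique(coverage$nutrient), collapse = ", "),
      paste(unique(coverage$item_id), collapse = ", ")),
      class = "plantshift_coverage_error")
  }

  keys <- distinct(items, across(any_of(c("scenario", "basis"))))
  items |>
    inner_join(select(nutrients, "item_id", "nutrient", "unit", "value"),
               by = "item_id", relationship = "many-to-many") |>
    group_by(across(any_of(c("scenario", "basis"))),
             .data$nutrient, .data$unit) |>
    summarise(supply = sum(.data$amount_g / 1000 * .data$value),
              .groups = "drop") |>
    # zero-fill nutrients absent only because the diet is empty
    full_join_zero(keys, nutrient_set)
}

# complete scenario x nutrient grid with zero supply
full_join_zero <- function(supplied, keys, nutrient_set) {
  if (nrow(keys) == 0) keys <- tibble(scenario = "BAU")
  grid <- tidyr::crossing(keys, nutrient_set)
  grid |>
    left_join(supplied, by = intersect(names(grid), names(supplied))) |>
    mutate(supply = dplyr::coalesce(.data$supply, 0))
}

#' Score a nutrient supply against a recommendation
#'
#' Normalised deviation `score = supply / threshold - 1`, so 0 marks the
#' recommended level. A `minimum`-type recommendation is met when supply is
#' at or above the threshold (score >= 0); a `limit`-type nutrient (sodium,
#' saturated fat) is met when supply is at or below it (score <= 0).
#'
#' @param supply Amount/day (vectorised).
#' @param threshold Recommended amount/day (> 0).
#' @param direction `"minimum"` or `"limit"`.
#' @return Tibble with `score` and `meets`.
#' @export
adequacy_score <- function(supply, threshold, direction) {
  if (any(threshold <= 0)) {
    abort("recommendation thresholds must be > 0",
          class = "plantshift_data_error")
  }
  if (!all(direction %in% c("minimum", "limit"))) {
    abort("direction must be 'minimum' or 'limit'",
          class = "plantshift_data_error")
  }
  score <- supply / threshold - 1
  tibble(score = score,
         meets = if_else(direction == "minimum", score >= 0, score <= 0))
}

#' Nutritional adequacy report
#'
#' Scores every scenario x nutrient combination against the database's
#' recommendation table and expresses each supply as a signed percent
#' change versus the baseline scenario. Nutrients without a recommendation
#' row (if any) are reported unscored. Energy is not scored.
#'
#' @param scenarios Stacked diet-profile tibble including the baseline.
#' @param db A [food_db()].
#' @param quantile Composition quantile to evaluate.
#' @param baseline Baseline scenario name (default `"BAU"`).
#' @return An `adequacy_report` tibble: `scenario`, `basis` (if present),
#'   `nutrient`, `unit`, `supply`, `threshold`, `direction`, `score`,
#'   `meets`, `pct_change_vs_bau`.
#' @export
adequacy_report <- function(scenarios, db,
                            quantile = c("median", "q25", "q75"),
                            baseline = "BAU") {
  quantile <- match.arg(quantile)
  if (!baseline %in% scenarios$scenario) {
    abort(sprintf("baseline scenario '%s' missing from input", baseline),
          class = "plantshift_usage_error")
  }
  supplies <- nutrient_supply(scenarios, db, quantile)
  by_base <- intersect(c("basis", "nutrient"), names(supplies))
  base <- supplies |>
    filter(.data$scenario == baseline) |>
    select(all_of(by_base), bau_supply = "supply")
  out <- supplies |>
    left_join(base, by = by_base) |>
    left_join(select(db$recommendations, "nutrient", "threshold", "direction"),
              by = "nutrient") |>
    mutate(
      pct_change_vs_bau = if_else(.data$bau_supply > 0,
        100 * (.data$supply - .data$bau_supply) / .data$bau_supply,
        NA_real_)
    )
  scored <- adequacy_score(
    out$supply,
    if_else(is.na(out$threshold), 1, out$threshold),
    dplyr::coalesce(out$direction, "minimum"))
  out$score <- if_else(is.na(out$threshold), NA_real_, scored$score)
  out$meets <- if_else(is.na(out$threshold), NA, scored$meets)
  out <- out |>
    select(any_of(c("scenario", "basis")), "nutrient", "unit", "supply",
           "threshold", "direction", "score", "meets", "pct_change_vs_bau")
  class(out) <- c("adequacy_report", class(out))
  attr(out, "quantile") <- quantile
  attr(out, "baseline") <- baseline
  out
}
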