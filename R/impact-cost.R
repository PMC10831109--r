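#' Environmental footprint of a diet
#'
#' Per-person-per-day totals for greenhouse gas emissions (`ghge`,
#' kg CO2e), cropland use (`lu`, m2) and consumptive blue freshwater use
#' (`wu`, L): `total = sum over items of amount_kg x intensity per kg` at
#' the chosen quantile, with per-group contributions and shares. The
#' system boundary (cradle-to-consumer, including consumer cooking) is a
#' property of the footprint data, carried in the database's
#' `boundary_note`, not recomputed here.
#'
#' @param diet Diet-profile tibble (one or more scenarios), consumption
#'   stage.
#' @param db A [food_db()].
#' @param quantile `"median"`, `"q25"` or `"q75"` intensities.
#' @return An `impact_result` tibble: `scenario` (`basis` if present),
#'   `indicator`, `unit`, `group`, `contribution`, `total`, `share`.
#'   Shares are `NA` when a total is zero (empty diet).
#' @export
total_impact <- function(diet, db, quantile = c("median", "q25", "q75")) {
  quantile <- match.arg(quantile)
  stopifnot(inherits(db, "food_db"))
  items <- allocate_items(diet, db)
  fp <- pick_quantile(db$footprints, quantile)

  used <- distinct(items, .data$item_id)
  indicators <- distinct(db$footprints, .data$indicator, .data$unit)
  coverage <- tidyr::crossing(used, indicator = indicators$indicator) |>
    anti_join(fp, by = c("item_id", "indicator"))
  if (nrow(coverage) > 0) {
    abort(sprintf(
      "footprint table lacks %s",
      paste(sprintf("%s for %s", coverage$indicator, coverage$item_id),
            collapse = "; ")),
      class = "plantshift_coverage_error")
  }

  out <- items |>
    inner_join(select(fp, "item_id", "indicator", "unit", "value"),
               by = "item_id", relationship = "many-to-many") |>
    group_by(across(any_of(c("scenario", "basis"))),
             .data$indicator, .data$unit, .data$group) |>
    summarise(contribution = sum(.data$amount_g / 1000 * .data$value),
              .groups = "drop_last") |>
    mutate(total = sum(.data$contribution),
           share = if_else(.data$total > 0,
                           .data$contribution / .data$total, NA_real_)) |>
    ungroup() |>
    mutate(unit = sub("/kg$", "/day", .data$unit))
  class(out) <- c("impact_result", class(out))
  attr(out, "quantile") <- quantile
  out
}

#' Signed percent change versus a baseline
#'
#' `100 * (value - baseline) / baseline`. A reduction comes out negative;
#' reporting layers may render -52 as "52% reduction".
#'
#' @param value,baseline Numeric vectors; `baseline` must be positive.
#' @return Numeric vector of signed percentages.
#' @export
percent_change <- function(value, baseline) {
  if (any(baseline <= 0)) {
    abort("percent_change() needs a positive baseline",
          class = "plantshift_domain_error")
  }
  100 * (value - baseline) / baseline
}

#' Share of dietary energy from animal-source foods
#'
#' @param diet Diet-profile tibble (a single scenario).
#' @param db A [food_db()].
#' @return Proportion in `[0, 1]`.
#' @export
asf_energy_share <- function(diet, db) {
  en <- energy_of(diet, db)
  total <- sum(en$kcal)
  if (total <= 0) {
    abort("diet has zero total energy", class = "plantshift_domain_error")
  }
  sum(en$kcal[group_class(en$group) == "asf"]) / total
}

#' Daily food expenditure
#'
#' Cost per person per day at a price quantile. Two aggregation methods:
#' `"group_quantile"` (default) takes the requested percentile of the
#' pooled within-group item price points and multiplies it by the group
#' amount — a spread bound reflecting where in a group's price range a
#' consumer buys, not a distributional confidence interval;
#' `"item_quantile"` sums `item amount x item price(quantile)` directly.
#'
#' @param diet Diet-profile tibble (one or more scenarios).
#' @param db A [food_db()].
#' @param quantile `"median"`, `"q25"` or `"q75"` prices.
#' @param method Aggregation method, see above.
#' @return An `expenditure_result` tibble: `scenario` (`basis` if present),
#'   `currency`, `group`, `cost`, `total`, `share`.
#' @export
daily_expenditure <- function(diet, db, quantile = c("median", "q25", "q75"),
                              method = c("group_quantile", "item_quantile")) {
  quantile <- match.arg(quantile)
  method <- match.arg(method)
  stopifnot(inherits(db, "food_db"))
  items <- allocate_items(diet, db)

  missing <- setdiff(unique(items$item_id), db$prices$item_id)
  if (length(missing) > 0) {
    abort(sprintf("price table lacks item(s): %s",
                  paste(missing, collapse = ", ")),
          class = "plantshift_coverage_error")
  }
  currency <- unique(db$prices$currency)[1]
  p <- c(q25 = 0.25, median = 0.5, q75 = 0.75)[[quantile]]

  if (method == "item_quantile") {
    pr <- pick_quantile(db$prices, quantile)
    out <- items |>
      inner_join(select(pr, "item_id", "value"), by = "item_id") |>
      group_by(across(any_of(c("scenario", "basis"))), .data$group) |>
      summarise(cost = sum(.data$amount_g / 1000 * .data$value),
                .groups = "drop")
  } else {
    group_price <- db$prices |>
      inner_join(select(db$items, "item_id", "group"), by = "item_id") |>
      group_by(.data$group) |>
      summarise(price = unname(quantile(c(.data$q25, .data$median, .data$q75),
                                        probs = p, type = 7)),
                .groups = "drop")
    out <- group_amounts(items) |>
      inner_join(group_price, by = "group") |>
      group_by(across(any_of(c("scenario", "basis"))), .data$group) |>
      summarise(cost = sum(.data$amount_g / 1000 * .data$price),
                .groups = "drop")
  }
  out <- out |>
    group_by(across(any_of(c("scenario", "basis")))) |>
    mutate(currency = currency,
           total = sum(.data$cost),
           share = if_else(.data$total > 0, .data$cost / .data$total,
                           NA_real_)) |>
    ungroup() |>
    select(any_of(c("scenario", "basis")), "currency", "group", "cost",
           "total", "share")
  class(out) <- c("expenditure_result", class(out))
  attr(out, "quantile") <- quantile
  attr(out, "method") <- method
  out
}

#' Scenario-level impact summary versus baseline
#'
#' Wraps [total_impact()] into one row per scenario x indicator with the
#' signed percent change against the baseline scenario.
#'
#' @inheritParams adequacy_report
#' @return An `impact_report` tibble: `scenario` (`basis` if present),
#'   `indicator`, `unit`, `total`, `pct_change_vs_bau`.
#' @export
impact_report <- function(scenarios, db,
                          quantile = c("median", "q25", "q75"),
                          baseline = "BAU") {
  quantile <- match.arg(quantile)
  if (!baseline %in% scenarios$scenario) {
    abort(sprintf("baseline scenario '%s' missing from input", baseline),
          class = "plantshift_usage_error")
  }
  contrib <- total_impact(scenarios, db, quantile)
  totals <- contrib |>
    distinct(across(any_of(c("scenario", "basis"))), .data$indicator,
             .data$unit, .data$total)
  by_cols <- intersect(c("basis", "indicator"), names(totals))
  base <- totals |>
    filter(.data$scenario == baseline) |>
    select(all_of(by_cols), bau_total = "total")
  out <- totals |>
    left_join(base, by = by_cols) |>
    mutate(pct_change_vs_bau = percent_change(.data$total, .data$bau_total)) |>
    select(-"bau_total")
  class(out) <- c("impact_report", class(out))
  attr(out, "quantile") <- quantile
  attr(out, "baseline") <- baseline
  out
}

#' Scenario-level expenditure summary versus baseline
#'
#' Daily cost at the lower quartile, median and upper quartile price
#' levels, with the percent change of the median cost against the baseline
#' scenario.
#'
#' @inheritParams daily_expenditure
#' @param scenarios Stacked diet-profile tibble including the baseline.
#' @param baseline Baseline scenario name.
#' @return An `expenditure_report` tibble: `scenario` (`basis` if present),
#'   `currency`, `q25`, `median`, `q75`, `pct_change_vs_bau`.
#' @export
expenditure_report <- function(scenarios, db, baseline = "BAU",
                               method = c("group_quantile", "item_quantile")) {
  method <- match.arg(method)
  if (!baseline %in% scenarios$scenario) {
    abort(sprintf("baseline scenario '%s' missing from input", baseline),
          class = "plantshift_usage_error")
  }
  per_q <- map_dfr(c("q25", "median", "q75"), function(q) {
    daily_expenditure(scenarios, db, quantile = q, method = method) |>
      as_tibble() |>
      distinct(across(any_of(c("scenario", "basis"))), .data$currency,
               .data$total) |>
      mutate(quantile = q)
  })
  out <- per_q |>
    tidyr::pivot_wider(names_from = "quantile", values_from = "total")
  by_cols <- intersect("basis", names(out))
  base <- out |>
    filter(.data$scenario == baseline) |>
    select(all_of(c(by_cols, "currency")), bau_median = "median")
  out <- out |>
    left_join(base, by = c(by_cols, "currency")) |>
    mutate(pct_change_vs_bau = percent_change(.data$median, .data$bau_median)) |>
    select(-"bau_median")
  class(out) <- c("expenditure_report", class(out))
  attr(out, "baseline") <- baseline
  attr(out, "method") <- method
  out
}
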