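#' Quantile sweep over all diet metrics
#'
#' Recomputes every downstream metric — footprint totals, daily cost and
#' nutrient supplies — at each requested quantile of the item-level data,
#' recording the quantile used as provenance. One row per scenario x basis
#' x quantile.
#'
#' @param scenarios Stacked diet-profile tibble.
#' @param db A [food_db()].
#' @param quantiles Subset of `c("q25", "median", "q75")`.
#' @param cost_method Passed to [daily_expenditure()].
#' @return Wide tibble: `scenario`, `basis`, `quantile`, one column per
#'   footprint indicator (`ghge`, `lu`, `wu`), `cost`, and one column per
#'   nutrient.
#' @export
quantile_sweep <- function(scenarios, db,
                           quantiles = c("q25", "median", "q75"),
                           cost_method = c("group_quantile", "item_quantile")) {
  cost_method <- match.arg(cost_method)
  quantiles <- match.arg(quantiles, several.ok = TRUE)
  degenerate <- all(db$footprints$q25 == db$footprints$q75) &&
    all(db$prices$q25 == db$prices$q75) &&
    all(db$nutrients$q25 == db$nutrients$q75)
  if (degenerate) {
    warn("all quantile triplets are degenerate (q25 = median = q75); sweep levels will coincide")
  }
  if (!"basis" %in% names(scenarios)) scenarios$basis <- "mass"

  map_dfr(quantiles, function(q) {
    imp <- total_impact(scenarios, db, quantile = q) |>
      as_tibble() |>
      distinct(.data$scenario, .data$basis, .data$indicator, .data$total) |>
      tidyr::pivot_wider(names_from = "indicator", values_from = "total")
    cost <- daily_expenditure(scenarios, db, quantile = q,
                              method = cost_method) |>
      as_tibble() |>
      distinct(.data$scenario, .data$basis, cost = .data$total)
    nut <- nutrient_supply(scenarios, db, quantile = q) |>
      select("scenario", "basis", "nutrient", "supply") |>
      tidyr::pivot_wider(names_from = "nutrient", values_from = "supply")
    imp |>
      inner_join(cost, by = c("scenario", "basis")) |>
      inner_join(nut, by = c("scenario", "basis")) |>
      mutate(quantile = q, .after = "basis")
  })
}

#' Conscious-consumer reallocation
#'
#' Bounds the effect of within-group item choice: inside every food group
#' the whole group amount is moved onto the single item that optimises the
#' objective (cheapest, lowest-footprint, most nutritious, ...) at the
#' stated quantile. Group totals are unchanged. Objectives are strings of
#' the form `min_<attr>` or `max_<attr>` where `<attr>` is `cost`, a
#' footprint indicator (`ghge`, `lu`, `wu`) or a nutrient name. Ties break
#' towards the lexicographically first item id.
#'
#' @param diet Diet-profile tibble.
#' @param db A [food_db()].
#' @param objective E.g. `"min_cost"`, `"min_ghge"`, `"max_protein"`.
#' @param quantile Data quantile at which items are compared.
#' @return An item-level diet-profile tibble.
#' @export
conscious_consumer <- function(diet, db, objective = "min_cost",
                               quantile = c("median", "q25", "q75")) {
  quantile <- match.arg(quantile)
  stopifnot(inherits(db, "food_db"))
  m <- regmatches(objective, regexec("^(min|max)_(.+)$", objective))[[1]]
  if (length(m) != 3) {
    abort("objective must look like 'min_cost', 'min_ghge' or 'max_protein'",
          class = "plantshift_usage_error")
  }
  sense <- m[2]; attr_name <- m[3]

  values <- item_attribute(db, attr_name, quantile)
  groups <- group_amounts(diet)
  missing <- db$items |>
    filter(.data$group %in% groups$group) |>
    anti_join(values, by = "item_id")
  if (nrow(missing) > 0) {
    abort(sprintf("attribute '%s' unavailable for item(s): %s", attr_name,
                  paste(missing$item_id, collapse = ", ")),
          class = "plantshift_coverage_error")
  }

  best <- db$items |>
    select("item_id", "group") |>
    inner_join(values, by = "item_id") |>
    arrange(.data$group,
            if (sense == "min") .data$value else -.data$value,
            .data$item_id) |>
    group_by(.data$group) |>
    slice(1) |>
    ungroup() |>
    select("group", "item_id")

  groups |>
    inner_join(best, by = "group") |>
    select(any_of(c("scenario", "basis", "stage")), "group", "item_id",
           "amount_g")
}

item_attribute <- function(db, attr_name, quantile) {
  if (attr_name == "cost") {
    pick_quantile(db$prices, quantile) |> select("item_id", "value")
  } else if (attr_name %in% unique(db$footprints$indicator)) {
    pick_quantile(filter(db$footprints, .data$indicator == attr_name),
                  quantile) |> select("item_id", "value")
  } else if (attr_name %in% unique(db$nutrients$nutrient)) {
    pick_quantile(filter(db$nutrients, .data$nutrient == attr_name),
                  quantile) |> select("item_id", "value")
  } else {
    abort(sprintf("unknown objective attribute '%s'", attr_name),
          class = "plantshift_coverage_error")
  }
}

#' Compare functional units
#'
#' Ratio of energy-basis to mass-basis totals per scenario and indicator,
#' flagging scenarios whose energy-basis footprint is below the mass-basis
#' one.
#'
#' @param results_mass,results_energy [impact_report()] outputs (or any
#'   tibbles with `scenario`, `indicator`, `total`) for the same scenario
#'   set under each basis.
#' @return Tibble: `scenario`, `indicator`, `total_mass`, `total_energy`,
#'   `ratio`, `below_one`.
#' @export
functional_unit_comparison <- function(results_mass, results_energy) {
  m <- as_tibble(results_mass) |>
    select("scenario", "indicator", total_mass = "total")
  e <- as_tibble(results_energy) |>
    select("scenario", "indicator", total_energy = "total")
  if (!setequal(unique(m$scenario), unique(e$scenario))) {
    abort("mass and energy results cover different scenario sets",
          class = "plantshift_usage_error")
  }
  m |>
    inner_join(e, by = c("scenario", "indicator")) |>
    mutate(ratio = .data$total_energy / .data$total_mass,
           below_one = .data$ratio < 1)
}
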