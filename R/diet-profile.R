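#' Diet profiles
#'
#' A diet profile is a plain tibble of per-capita amounts with columns
#' `scenario`, `basis` (`mass`/`energy`: the functional unit the scenario
#' was built under), `stage` (`supply` before household loss and waste,
#' `consumption` after), `group`, optional `item_id` (`NA` for group-level
#' rows) and `amount_g` (g/person/day). Helpers below construct, aggregate
#' and reallocate profiles; all analysis functions accept group-level or
#' item-level profiles and several scenarios stacked in one table.
#'
#' @param amounts Named numeric of g/person/day per food group, or a tibble
#'   with `group` and `amount_g` (and optionally `item_id`).
#' @param scenario,basis,stage Metadata columns to attach.
#' @return A diet-profile tibble.
#' @export
diet_profile <- function(amounts, scenario = "BAU", basis = "mass",
                         stage = "consumption") {
  if (is.numeric(amounts) && !is.null(names(amounts))) {
    amounts <- tibble(group = names(amounts), amount_g = unname(amounts))
  }
  amounts <- as_tibble(amounts)
  require_columns(amounts, "diet profile", c("group", "amount_g"))
  assert_known_groups(amounts$group, "diet profile")
  if (any(amounts$amount_g < 0)) {
    abort("diet amounts must be non-negative", class = "plantshift_data_error")
  }
  if (!"item_id" %in% names(amounts)) amounts$item_id <- NA_character_
  amounts |>
    mutate(scenario = scenario, basis = basis, stage = stage) |>
    select("scenario", "basis", "stage", "group", "item_id", "amount_g")
}

#' @rdname diet_profile
#' @param profile A diet-profile tibble.
#' @export
group_amounts <- function(profile) {
  profile |>
    group_by(across(any_of(c("scenario", "basis", "stage"))), .data$group) |>
    summarise(amount_g = sum(.data$amount_g), .groups = "drop")
}

#' Allocate group amounts to items
#'
#' Splits each group-level amount across that group's database items:
#' equally by default, or by the within-group shares of a reference
#' item-level profile (e.g. the baseline diet) where available. Item-level
#' rows in `profile` pass through unchanged.
#'
#' @param profile A diet-profile tibble.
#' @param db A [food_db()].
#' @param shares Optional item-level profile supplying within-group shares.
#' @return An item-level diet-profile tibble.
#' @export
allocate_items <- function(profile, db, shares = NULL) {
  stopifnot(inherits(db, "food_db"))
  has_item <- !is.na(profile$item_id)
  done <- profile[has_item, , drop = FALSE]
  todo <- profile[!has_item, , drop = FALSE]
  if (nrow(todo) == 0) return(profile)

  share_tbl <- db$items |>
    select("item_id", "group") |>
    arrange(.data$group, .data$item_id) |>
    group_by(.data$group) |>
    mutate(share = 1 / dplyr::n()) |>
    ungroup()
  if (!is.null(shares)) {
    ref <- shares |>
      filter(!is.na(.data$item_id)) |>
      group_by(.data$group) |>
      mutate(ref_share = if (sum(.data$amount_g) > 0) {
        .data$amount_g / sum(.data$amount_g)
      } else NA_real_) |>
      ungroup() |>
      select("item_id", "ref_share")
    share_tbl <- share_tbl |>
      left_join(ref, by = "item_id") |>
      mutate(share = dplyr::coalesce(.data$ref_share, .data$share)) |>
      select(-"ref_share")
  }

  expanded <- todo |>
    select(-"item_id") |>
    inner_join(share_tbl, by = "group", relationship = "many-to-many") |>
    mutate(amount_g = .data$amount_g * .data$share) |>
    select(-"share")
  missing <- setdiff(todo$group, share_tbl$group)
  if (length(missing) > 0) {
    abort(sprintf("database has no items for group(s): %s",
                  paste(missing, collapse = ", ")),
          class = "plantshift_coverage_error")
  }
  bind_rows(done, expanded) |>
    select("scenario", "basis", "stage", "group", "item_id", "amount_g") |>
    arrange(.data$scenario, .data$basis, .data$group, .data$item_id)
}

#' Convert a supply profile to consumption
#'
#' Applies household loss and waste fractions:
#' `consumption = supply * (1 - waste_fraction)`. Item-level rows use the
#' item's fraction; group-level rows use the group mean fraction.
#'
#' @param supply A supply-stage diet profile.
#' @param db A [food_db()] carrying `waste_fraction` per item.
#' @return The profile with reduced amounts and `stage = "consumption"`.
#' @export
apply_waste <- function(supply, db) {
  stopifnot(inherits(db, "food_db"))
  if (!all(supply$stage == "supply")) {
    abort("apply_waste() expects a supply-stage profile",
          class = "plantshift_usage_error")
  }
  if (any(db$items$waste_fraction >= 1 | db$items$waste_fraction < 0)) {
    abort("waste fractions must be in [0, 1)", class = "plantshift_data_error")
  }
  item_w <- db$items |> select("item_id", "waste_fraction")
  group_w <- db$items |>
    group_by(.data$group) |>
    summarise(group_waste = mean(.data$waste_fraction), .groups = "drop")
  supply |>
    left_join(item_w, by = "item_id") |>
    left_join(group_w, by = "group") |>
    mutate(
      waste = dplyr::coalesce(.data$waste_fraction, .data$group_waste, 0),
      amount_g = .data$amount_g * (1 - .data$waste),
      stage = "consumption"
    ) |>
    select("scenario", "basis", "stage", "group", "item_id", "amount_g")
}

#' Dietary energy content
#'
#' Total and per-group kcal/person/day of a consumption-stage profile.
#' Group-level rows are split equally across the group's items to look up
#' energy densities.
#'
#' @param diet A diet-profile tibble.
#' @param db A [food_db()].
#' @return Tibble with `scenario`, `basis`, `group`, `kcal`, plus the
#'   per-scenario total repeated in `total_kcal`.
#' @export
energy_of <- function(diet, db) {
  stopifnot(inherits(db, "food_db"))
  items <- allocate_items(diet, db)
  dens <- db$items |> select("item_id", "energy_density_kcal_g")
  joined <- items |> left_join(dens, by = "item_id")
  no_dens <- joined$item_id[is.na(joined$energy_density_kcal_g)]
  if (length(no_dens) > 0) {
    abort(sprintf("missing energy density for item(s): %s",
                  paste(unique(no_dens), collapse = ", ")),
          class = "plantshift_data_error")
  }
  joined |>
    group_by(across(any_of(c("scenario", "basis"))), .data$group) |>
    summarise(kcal = sum(.data$amount_g * .data$energy_density_kcal_g),
              .groups = "drop_last") |>
    mutate(total_kcal = sum(.data$kcal)) |>
    ungroup()
}

# group-level mean energy density (kcal/g), used when substitution converts
# kilocalories to grams at the group resolution
group_energy_density <- function(db) {
  db$items |>
    group_by(.data$group) |>
    summarise(energy_density_kcal_g = mean(.data$energy_density_kcal_g),
              .groups = "drop")
}
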