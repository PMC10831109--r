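#' Define a replacement scenario
#'
#' A scenario removes a fraction of selected food groups from the baseline
#' diet and reallocates the removed amount to replacement groups under a
#' functional unit: on a mass basis the grams removed equal the grams
#' added; on an energy basis the replacement grams are chosen so the
#' kilocalories added equal the kilocalories removed (per mapping,
#' `grams = kcal / energy density`). Replacement targets can carry caps
#' (upper reference values, g/person/day); a target at its cap overflows to
#' the next-weighted target, ties broken by group name, and an error is
#' raised if removal cannot be fully reallocated.
#'
#' @param name Scenario name (free text; `"BAU"` conventionally denotes the
#'   unmodified baseline).
#' @param removed_groups Character vector of groups to reduce.
#' @param reduction_fraction Fraction of each removed group's amount taken
#'   out, in (0, 1]; 1 for vegan/vegetarian removals, 0.5 for flexitarian.
#' @param mode `"pba"`, `"wf"` or `"none"` (no substitution; baseline
#'   passes through unchanged).
#' @param replacement_map Named list: removed group -> tibble with `target`
#'   and `weight` columns. Ignored when `mode = "none"`.
#' @param caps Named numeric of maximum g/person/day per target group
#'   (e.g. EAT-Lancet-style upper reference values). Unlisted groups are
#'   uncapped.
#' @param functional_unit `"mass"` or `"energy"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, removed_groups = character(),
                          reduction_fraction = 1,
                          mode = c("pba", "wf", "none"),
                          replacement_map = list(),
                          caps = numeric(),
                          functional_unit = c("mass", "energy")) {
  mode <- match.arg(mode)
  functional_unit <- match.arg(functional_unit)
  assert_known_groups(removed_groups, "removed_groups")
  assert_known_groups(names(caps), "caps")
  if (mode != "none") {
    if (!(reduction_fraction > 0 && reduction_fraction <= 1)) {
      abort("reduction_fraction must be in (0, 1]",
            class = "plantshift_spec_error")
    }
    replacement_map <- map(replacement_map, function(m) {
      m <- as_tibble(m)
      require_columns(m, "replacement_map", c("target", "weight"))
      assert_known_groups(m$target, "replacement_map targets")
      if (any(m$weight <= 0)) {
        abort("replacement weights must be positive",
              class = "plantshift_spec_error")
      }
      arrange(m, desc(.data$weight), .data$target)
    })
    unmapped <- setdiff(removed_groups, names(replacement_map))
    if (length(unmapped) > 0) {
      abort(sprintf("no replacement mapping for removed group(s): %s",
                    paste(unmapped, collapse = ", ")),
            class = "plantshift_spec_error")
    }
  }
  structure(
    list(name = name, removed_groups = removed_groups,
         reduction_fraction = reduction_fraction, mode = mode,
         replacement_map = replacement_map, caps = caps,
         functional_unit = functional_unit),
    class = "scenario_spec"
  )
}

# default replacement weights for whole-food substitution, seeded from the
# canonical scenario table's vegan whole-food deltas (g added per group)
wf_replacement_weights <- function() {
  tibble(
    target = c("Vegetables", "Fruits", "Legumes", "Grains", "Nuts",
               "Plant fats"),
    weight = c(165, 150, 150, 100, 42, 6) / 613
  )
}

# upper reference values (g/person/day) for whole-food targets, seeded from
# the canonical table's maxima
eat_lancet_caps <- function() {
  c(Legumes = 150, Nuts = 50, Vegetables = 330, Fruits = 300, Grains = 270)
}

pba_replacement_map <- function(groups = c("Meats", "Eggs", "Dairy",
                                           "Seafood", "Snacks")) {
  # eggs route to PB meat: no PB-egg category exists
  target <- c(Meats = "Plant-based Meat", Eggs = "Plant-based Meat",
              Dairy = "Plant-based Dairy", Seafood = "Plant-based Seafood",
              Snacks = "Plant-based Snacks")
  map(setNames(groups, groups),
      function(g) tibble(target = target[[g]], weight = 1))
}

wf_replacement_map <- function(groups) {
  wf <- wf_replacement_weights()
  out <- map(setNames(groups, groups), function(g) {
    if (g == "Snacks") tibble(target = "Plant-based Snacks", weight = 1) else wf
  })
  out
}

#' Default scenario set
#'
#' The seven canonical scenarios: baseline (`BAU`) plus vegan, vegetarian
#' and flexitarian variants replacing animal-source foods with either
#' plant-based alternatives (`*PBA`) or whole foods (`*WHOLE`). Vegan and
#' flexitarian scenarios also swap conventional snacks for their
#' plant-based counterparts; vegetarian scenarios retain eggs, dairy and
#' snacks. Flexitarian scenarios halve each replaced group.
#'
#' @param functional_unit `"mass"` or `"energy"`.
#' @param caps Named numeric of whole-food caps (defaults to
#'   EAT-Lancet-style upper reference values).
#' @return Named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function(functional_unit = c("mass", "energy"),
                              caps = eat_lancet_caps()) {
  functional_unit <- match.arg(functional_unit)
  all_asf_plus_snacks <- c("Meats", "Eggs", "Dairy", "Seafood", "Snacks")
  meat_seafood <- c("Meats", "Seafood")
  list(
    BAU = scenario_spec("BAU", mode = "none",
                        functional_unit = functional_unit),
    VGNPBA = scenario_spec(
      "VGNPBA", all_asf_plus_snacks, 1, "pba",
      pba_replacement_map(all_asf_plus_snacks),
      functional_unit = functional_unit),
    VGNWHOLE = scenario_spec(
      "VGNWHOLE", all_asf_plus_snacks, 1, "wf",
      wf_replacement_map(all_asf_plus_snacks), caps = caps,
      functional_unit = functional_unit),
    VGTPBA = scenario_spec(
      "VGTPBA", meat_seafood, 1, "pba",
      pba_replacement_map(meat_seafood),
      functional_unit = functional_unit),
    VGTWHOLE = scenario_spec(
      "VGTWHOLE", meat_seafood, 1, "wf",
      wf_replacement_map(meat_seafood), caps = caps,
      functional_unit = functional_unit),
    FLXPBA = scenario_spec(
      "FLXPBA", all_asf_plus_snacks, 0.5, "pba",
      pba_replacement_map(all_asf_plus_snacks),
      functional_unit = functional_unit),
    FLXWHOLE = scenario_spec(
      "FLXWHOLE", all_asf_plus_snacks, 0.5, "wf",
      wf_replacement_map(all_asf_plus_snacks), caps = caps,
      functional_unit = functional_unit)
  )
}

#' Apply a replacement scenario to a baseline diet
#'
#' Operates at food-group resolution on a consumption-stage profile.
#' Removal: `reduction_fraction * baseline amount` per removed group.
#' Reallocation follows the spec's replacement map and functional unit (see
#' [scenario_spec()]); groups that are neither removed nor targets pass
#' through unchanged, and `mode = "none"` returns the baseline (relabelled)
#' as-is.
#'
#' @param bau Baseline diet profile at consumption stage.
#' @param spec A [scenario_spec()].
#' @param db A [food_db()] (needed for energy densities on the energy
#'   basis).
#' @return A group-level diet-profile tibble for the scenario.
#' @export
substitute_diet <- function(bau, spec, db) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(db, "food_db"))
  if (!all(bau$stage == "consumption")) {
    abort("substitute_diet() expects a consumption-stage baseline",
          class = "plantshift_usage_error")
  }
  base <- group_amounts(bau)
  amounts <- setNames(rep(0, length(food_groups())), food_groups())
  amounts[base$group] <- base$amount_g

  if (spec$mode == "none") {
    return(diet_profile(amounts, scenario = spec$name,
                        basis = spec$functional_unit,
                        stage = "consumption"))
  }

  dens_tbl <- group_energy_density(db)
  dens <- setNames(dens_tbl$energy_density_kcal_g, dens_tbl$group)
  energy <- spec$functional_unit == "energy"

  for (g in spec$removed_groups) {
    removed_g <- spec$reduction_fraction * amounts[[g]]
    amounts[g] <- amounts[[g]] - removed_g
    if (removed_g <= 0) next

    targets <- spec$replacement_map[[g]]
    if (energy) {
      if (is.na(dens[g]) || dens[g] <= 0) {
        abort(sprintf("missing energy density for removed group '%s'", g),
              class = "plantshift_data_error")
      }
      pool <- removed_g * dens[[g]]   # kcal to reallocate
      tdens <- dens[targets$target]
      if (any(is.na(tdens) | tdens <= 0)) {
        abort(sprintf(
          "zero or missing energy density for replacement target(s): %s",
          paste(targets$target[is.na(tdens) | tdens <= 0], collapse = ", ")),
          class = "plantshift_data_error")
      }
    } else {
      pool <- removed_g                # grams to reallocate
    }

    # proportional allocation with cap waterfilling; capacity is expressed
    # in the functional unit (grams, or kcal = grams * density)
    live <- targets
    while (pool > 1e-9 && nrow(live) > 0) {
      desired <- pool * live$weight / sum(live$weight)
      cap_g <- unname(spec$caps[live$target])
      headroom_g <- ifelse(is.na(cap_g), Inf, pmax(cap_g - amounts[live$target], 0))
      capacity <- if (energy) headroom_g * dens[live$target] else headroom_g
      grant <- pmin(desired, capacity)
      add_g <- if (energy) grant / dens[live$target] else grant
      amounts[live$target] <- amounts[live$target] + add_g
      pool <- pool - sum(grant)
      saturated <- grant >= capacity - 1e-12
      if (!any(saturated)) break   # everything desired fit; pool now ~0
      live <- live[!saturated, , drop = FALSE]
    }
    if (pool > 1e-6) {
      abort(sprintf(
        "scenario '%s': all replacement targets for '%s' capped; %.3f %s unallocated",
        spec$name, g, pool, if (energy) "kcal" else "g"),
        class = "plantshift_infeasible_error")
    }
  }

  diet_profile(amounts, scenario = spec$name, basis = spec$functional_unit,
               stage = "consumption")
}

#' Build a set of scenarios
#'
#' Applies each [scenario_spec()] to the baseline and stacks the resulting
#' profiles; with `basis = "both"` the whole set is built under each
#' functional unit.
#'
#' @param bau Consumption-stage baseline profile.
#' @param db A [food_db()].
#' @param specs Named list of scenario specs (default [default_scenarios()]).
#' @param basis `"mass"`, `"energy"` or `"both"`.
#' @return A stacked diet-profile tibble (group level).
#' @export
build_scenarios <- function(bau, db, specs = NULL,
                            basis = c("mass", "energy", "both")) {
  basis <- match.arg(basis)
  bases <- if (basis == "both") c("mass", "energy") else basis
  map_dfr(bases, function(b) {
    sp <- specs %||% default_scenarios(functional_unit = b)
    sp <- map(sp, function(s) { s$functional_unit <- b; s })
    map_dfr(sp, substitute_diet, bau = bau, db = db)
  })
}

#' Load the canonical scenario table
#'
#' Reads the packaged fixture of published scenario quantities: 17 food
#' groups x 7 scenarios x 2 bases. Mass-basis rows are g/person/day;
#' energy-basis rows are kcal/person/day (the two coincide through each
#' group's energy density wherever a group is unchanged by substitution).
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Long tibble: `scenario`, `basis`, `group`, `amount`, `unit`.
#' @export
load_canonical_scenarios <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_scenarios.csv",
                                package = "plantshift", mustWork = TRUE)
  wide <- read_table_file(path)
  require_columns(wide, "canonical scenarios", c("group", "basis"))
  long <- wide |>
    tidyr::pivot_longer(-c("group", "basis"), names_to = "scenario",
                        values_to = "amount")
  if (anyNA(long$amount)) {
    bad <- long[is.na(long$amount), ]
    abort(sprintf("missing cell(s) in canonical table: %s",
                  paste(sprintf("%s/%s/%s", bad$group, bad$basis,
                                bad$scenario), collapse = "; ")),
          class = "plantshift_parse_error")
  }
  long |>
    mutate(unit = if_else(.data$basis == "mass", "g_per_day", "kcal_per_day")) |>
    select("scenario", "basis", "group", "amount", "unit")
}

#' @rdname load_canonical_scenarios
#' @param canonical Output of `load_canonical_scenarios()`.
#' @param db Optional [food_db()]; when given, energy-basis rows are
#'   converted from kcal to grams through group mean energy densities so
#'   every profile is usable by the downstream stages. Without a database
#'   only mass-basis profiles are returned.
#' @return A stacked consumption-stage diet-profile tibble.
#' @export
canonical_profiles <- function(canonical = load_canonical_scenarios(),
                               db = NULL) {
  mass <- canonical |>
    filter(.data$basis == "mass") |>
    mutate(item_id = NA_character_, stage = "consumption",
           amount_g = .data$amount) |>
    select("scenario", "basis", "stage", "group", "item_id", "amount_g")
  if (is.null(db)) return(mass)
  dens_tbl <- group_energy_density(db)
  energy <- canonical |>
    filter(.data$basis == "energy") |>
    left_join(dens_tbl, by = "group") |>
    mutate(item_id = NA_character_, stage = "consumption",
           amount_g = .data$amount / .data$energy_density_kcal_g) |>
    select("scenario", "basis", "stage", "group", "item_id", "amount_g")
  bind_rows(mass, energy)
}
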