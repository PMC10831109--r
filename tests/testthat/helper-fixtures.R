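# Hand-built fixtures with round numbers, used as arithmetic oracles.

degenerate <- function(x) tibble::tibble(q25 = x, median = x, q75 = x)

# Two single-item groups with round-number attributes:
#   meat_a:   2.0 kcal/g, waste 0.2, ghge 10, lu 5, wu 100, price 40/kg,
#             protein 80 g/kg, sodium 2000 mg/kg
#   legume_a: 0.8 kcal/g, waste 0,   ghge 1,  lu 1, wu 50,  price 100/kg,
#             protein 90 g/kg, sodium 50 mg/kg
simple_db <- function() {
  items <- tibble::tibble(
    item_id = c("meat_a", "legume_a"),
    group = c("Meats", "Legumes"),
    class = c("asf", "wf"),
    energy_density_kcal_g = c(2.0, 0.8),
    waste_fraction = c(0.2, 0),
    fortified_with = ""
  )
  nutrients <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(item_id = c("meat_a", "legume_a"),
                                    nutrient = "protein", unit = "g"),
                     degenerate(c(80, 90))),
    dplyr::bind_cols(tibble::tibble(item_id = c("meat_a", "legume_a"),
                                    nutrient = "sodium", unit = "mg"),
                     degenerate(c(2000, 50)))
  )
  footprints <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(item_id = c("meat_a", "legume_a"),
                                    indicator = "ghge", unit = "kg CO2e/kg"),
                     degenerate(c(10, 1))),
    dplyr::bind_cols(tibble::tibble(item_id = c("meat_a", "legume_a"),
                                    indicator = "lu", unit = "m2/kg"),
                     degenerate(c(5, 1))),
    dplyr::bind_cols(tibble::tibble(item_id = c("meat_a", "legume_a"),
                                    indicator = "wu", unit = "L/kg"),
                     degenerate(c(100, 50)))
  )
  prices <- dplyr::bind_cols(
    tibble::tibble(item_id = c("meat_a", "legume_a"), currency = "SEK"),
    degenerate(c(40, 100)))
  recommendations <- tibble::tibble(
    nutrient = c("protein", "sodium"), unit = c("g", "mg"),
    threshold = c(58, 2300), direction = c("minimum", "limit"),
    source_note = "fixture")
  food_db(items, nutrients, footprints, prices, recommendations)
}

# default synthetic study conditions, generated once per test session
default_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_database(synthetic_spec(seed = 101))
    cache
  }
})

default_bau <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- apply_waste(
        generate_bau_supply(synthetic_spec(seed = 101), default_db()),
        default_db())
    }
    cache
  }
})

default_scenario_profiles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_scenarios(default_bau(), default_db(), basis = "mass")
    }
    cache
  }
})

# canonical published baseline at consumption stage (group level, mass)
canonical_bau <- function() {
  canonical_profiles() |> dplyr::filter(scenario == "BAU")
}

canonical_cell <- function(tbl, scen, b, grp) {
  tbl$amount[tbl$scenario == scen & tbl$basis == b & tbl$group == grp]
}

profile_amount <- function(profile, scen, grp) {
  g <- group_amounts(profile)
  sum(g$amount_g[g$scenario == scen & g$group == grp])
}
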