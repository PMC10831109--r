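#' Specification for the synthetic food database
#'
#' The generator emulates the statistical structure of a national food
#' database paired with LCA, retail-price and waste data: animal-source
#' groups carry the largest footprints, plant-based alternatives (PBAs) sit
#' between them and whole plant foods; PBAs are fortified with B12, vitamin
#' D, calcium and iron and carry more sodium than the products they mimic;
#' within-group price and footprint dispersion is right-skewed (log-normal);
#' and the baseline diet contains no PBAs, legumes or soy foods.
#'
#' @param seed Integer; fixes every random draw.
#' @param items_per_group Number of items generated per food group (>= 1).
#' @param footprint_ordering Named list `indicator -> named numeric` of
#'   group median intensities per kg; defaults encode ASF > PBA > WF. After
#'   generation the realised group medians equal these values exactly
#'   (item draws are rescaled to a median multiplier of 1), so the ordering
#'   holds as strict inequalities on generated medians.
#' @param fortification_policy Character vector of nutrients added to
#'   fortifiable PBA groups (Plant-based Meat/Dairy/Seafood). Empty vector
#'   disables fortification.
#' @param sodium_uplift Multiplicative factor applied to a PBA group's
#'   sodium relative to the group it replaces (> 1 means saltier).
#' @param price_dispersion Log-scale sigma of within-group price spread.
#' @param footprint_dispersion,nutrient_dispersion,density_dispersion
#'   Log-scale sigmas for the other item-level spreads.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           items_per_group = 3L,
                           footprint_ordering = default_footprint_medians(),
                           fortification_policy = c("b12", "vitamin_d",
                                                    "calcium", "iron"),
                           sodium_uplift = 1.5,
                           price_dispersion = 0.5,
                           footprint_dispersion = 0.4,
                           nutrient_dispersion = 0.25,
                           density_dispersion = 0.15) {
  if (items_per_group < 1) {
    abort("items_per_group must be >= 1", class = "plantshift_spec_error")
  }
  structure(
    list(seed = as.integer(seed),
         items_per_group = as.integer(items_per_group),
         footprint_ordering = footprint_ordering,
         fortification_policy = fortification_policy,
         sodium_uplift = sodium_uplift,
         price_dispersion = price_dispersion,
         footprint_dispersion = footprint_dispersion,
         nutrient_dispersion = nutrient_dispersion,
         density_dispersion = density_dispersion),
    class = "synthetic_spec"
  )
}

#' Default synthetic group medians
#'
#' Magnitudes are loosely calibrated to Swedish LCA and discount-retail
#' scales (e.g. a beef/pork/chicken meat mix near 11 kg CO2e/kg, legumes
#' near 1), but are the package's own synthetic values, not measured data.
#'
#' @return Named list of named numeric vectors (one per indicator, plus
#'   `price` in SEK/kg and `energy_density` in kcal/g).
#' @export
default_footprint_medians <- function() {
  g <- food_groups()
  list(
    ghge = setNames(c(11, 2.5, 2.5, 1.4, 0.5, 4.5, 2.0, 0.8, 0.7, 0.3,
                      0.9, 3.0, 1.0, 2.0, 4.0, 6.0, 1.5), g),
    lu   = setNames(c(9, 2.5, 5, 1.9, 0.8, 2.0, 1.5, 0.4, 0.6, 0.3,
                      1.5, 2.5, 1.5, 8, 2.5, 5, 1.2), g),
    wu   = setNames(c(500, 300, 300, 100, 50, 300, 150, 150, 400, 100,
                      650, 700, 300, 4000, 500, 1500, 200), g),
    price = setNames(c(110, 110, 55, 60, 55, 150, 180, 35, 35, 15,
                       40, 80, 35, 130, 90, 95, 30), g),
    energy_density = setNames(c(1.75, 1.5, 1.4, 1.1, 0.55, 1.67, 1.55,
                                0.30, 0.73, 0.85, 2.94, 7.2, 1.0, 6.25,
                                3.94, 3.9, 0.42), g)
  )
}

# per-group household loss/waste fractions (FAO-style magnitudes)
default_waste_fractions <- function() {
  g <- food_groups()
  setNames(c(0.11, 0.09, 0.08, 0.07, 0.07, 0.08, 0.09, 0.19, 0.19, 0.17,
             0.12, 0.05, 0.08, 0.05, 0.05, 0.05, 0.05), g)
}

# nutrient content medians per kg of food, by group; b12 is zero for all
# plant groups so that an empty fortification policy yields B12-free plant
# items exactly
synthetic_nutrient_medians <- function() {
  cols <- c("protein", "fibre", "saturated_fat", "pufa", "sodium", "iron",
            "zinc", "calcium", "magnesium", "phosphorus", "selenium",
            "folate", "b12", "vitamin_c", "vitamin_d", "vitamin_e")
  m <- rbind(
    "Meats"               = c(200,  0, 40, 10, 2000, 15, 35,  100,  200, 1900, 100,   50, 20,   0,   5,   4),
    "Plant-based Meat"    = c(160, 50, 15, 30, 2000, 30, 15,  120,  400, 2500,  20,  300,  0,   0,   0,  10),
    "Eggs"                = c(125,  0, 31, 17, 1400, 18, 13,  560,  120, 2000, 200,  470, 20,   0,  20,  10),
    "Dairy"               = c( 60,  0, 25,  2,  600,  1,  6, 2000,  150, 1300,  20,   70, 10,  10,  15,   1),
    "Plant-based Dairy"   = c( 12, 10,  3,  8,  600,  2,  2,  100,   80,  600,   5,   30,  0,   0,   0,   5),
    "Seafood"             = c(180,  0,  8, 30, 1000,  5, 10,  200,  300, 2200, 300,  120, 50,   0, 120,  10),
    "Plant-based Seafood" = c(100, 30, 10, 25, 1000,  5,  5,  100,  150,  800,  30,  100,  0,   0,   0,   8),
    "Vegetables"          = c( 20, 25,  1,  2,  200,  8,  4,  400,  200,  400,   5,  500,  0, 300,   0,  10),
    "Fruits"              = c(  7, 20,  1,  1,   20,  3,  1,  150,  100,  150,   2,  150,  0, 350,   0,   5),
    "Potatoes"            = c( 20, 20,  1,  1,   60,  4,  4,   60,  220,  500,   3,  180,  0, 180,   0,   1),
    "Grains"              = c(110, 70,  3, 10, 3500, 30, 15,  300,  700, 2000,  50,  400,  0,   0,   0,  10),
    "Plant fats"          = c(  2,  0,150,350,  800,  1,  1,   20,   10,   20,   1,   10,  0,   0,  50, 300),
    "Legumes"             = c( 80, 70,  1,  3,   50, 22, 11,  450,  400, 1300,  20, 1500,  0,  10,   0,   3),
    "Nuts"                = c(200, 80, 50,250,  100, 30, 30,  800, 2300, 4500,  40,  600,  0,  10,   0, 150),
    "Snacks"              = c( 60, 20,100, 30, 4000, 15, 10,  400,  400, 1500,  30,  150,  0,   5,   5,  20),
    "Plant-based Snacks"  = c( 70, 80,180, 15, 4000, 50, 10,  400, 1600, 1500,  30,  100,  0,   0,   0,  15),
    "Other"               = c( 10,  5, 20,  5, 6000,  5,  2,  100,  100,  200,   5,   30,  0,  50,   0,   3)
  )
  colnames(m) <- cols
  m
}

nutrient_units <- function() {
  tibble::tribble(
    ~nutrient,        ~unit,
    "protein",        "g",
    "fibre",          "g",
    "saturated_fat",  "g",
    "pufa",           "g",
    "sodium",         "mg",
    "iron",           "mg",
    "zinc",           "mg",
    "calcium",        "mg",
    "magnesium",      "mg",
    "phosphorus",     "mg",
    "selenium",       "ug",
    "folate",         "ug",
    "b12",            "ug",
    "vitamin_c",      "mg",
    "vitamin_d",      "ug",
    "vitamin_e",      "mg"
  )
}

# fortification doses added per kg of fortified PBA product
fortification_doses <- function() {
  c(b12 = 3, vitamin_d = 20, calcium = 1200, iron = 14)
}

fortifiable_groups <- function() {
  c("Plant-based Meat", "Plant-based Dairy", "Plant-based Seafood")
}

# log-normal multipliers rescaled so their median is exactly 1; keeps the
# realised group median equal to the target while the spread stays
# right-skewed
median_one_multipliers <- function(n, sigma) {
  m <- exp(rnorm(n, 0, sigma))
  m / median(m)
}

# q25/q75 around an item median under a log-normal within-item spread
triplet <- function(med, sigma) {
  k <- exp(qnorm(0.75) * sigma)
  # 9 significant digits: far below any analysis tolerance, and short
  # enough that CSV serialisation round-trips byte-identically
  tibble(q25 = signif(med / k, 9), median = signif(med, 9),
         q75 = signif(med * k, 9))
}

slug <- function(x) gsub("[^a-z]+", "_", tolower(x))

#' Generate a synthetic food database
#'
#' Deterministic given the spec: the same spec yields byte-identical
#' databases. Group medians of every footprint indicator, price and energy
#' density equal the spec's target values exactly; item-level values spread
#' log-normally around them. PBA sodium is the replaced group's sodium
#' times `sodium_uplift`; fortified nutrients are added on top of the base
#' composition of fortifiable PBA groups.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated [food_db()].
#' @export
generate_database <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_database_impl(spec))
}

generate_database_impl <- function(spec) {
  groups <- food_group_table()
  n <- spec$items_per_group
  med <- spec$footprint_ordering
  nut_med <- synthetic_nutrient_medians()
  waste <- default_waste_fractions()
  doses <- fortification_doses()
  units <- nutrient_units()

  # sodium uplift for PBA groups relative to what they replace
  for (i in seq_len(nrow(groups))) {
    if (groups$class[i] == "pba") {
      nut_med[groups$group[i], "sodium"] <-
        spec$sodium_uplift * nut_med[groups$replaces[i], "sodium"]
    }
  }

  items <- list(); nutrients <- list(); footprints <- list(); prices <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups$group[i]
    ids <- sprintf("%s_%02d", slug(g), seq_len(n))
    fortified <- groups$class[i] == "pba" && g %in% fortifiable_groups() &&
      length(spec$fortification_policy) > 0

    dens <- signif(pmin(pmax(
      med$energy_density[[g]] * median_one_multipliers(n, spec$density_dispersion),
      0.1), 9), 9)
    items[[g]] <- tibble(
      item_id = ids, group = g, class = groups$class[i],
      energy_density_kcal_g = dens,
      waste_fraction = waste[[g]],
      fortified_with = if (fortified) {
        paste(sort(spec$fortification_policy), collapse = ";")
      } else "",
      boundary_note = "cradle-to-consumer (synthetic)"
    )

    fp <- map_dfr(c("ghge", "lu", "wu"), function(ind) {
      item_med <- med[[ind]][[g]] * median_one_multipliers(n, spec$footprint_dispersion)
      bind_cols(tibble(item_id = ids, indicator = ind,
                       unit = c(ghge = "kg CO2e/kg", lu = "m2/kg",
                                wu = "L/kg")[[ind]]),
                triplet(item_med, spec$footprint_dispersion))
    })
    footprints[[g]] <- fp

    pr_med <- med$price[[g]] * median_one_multipliers(n, spec$price_dispersion)
    prices[[g]] <- bind_cols(tibble(item_id = ids, currency = "SEK"),
                             triplet(pr_med, spec$price_dispersion))

    nutrients[[g]] <- map_dfr(units$nutrient, function(nm) {
      base <- nut_med[g, nm]
      item_med <- if (base > 0) {
        base * median_one_multipliers(n, spec$nutrient_dispersion)
      } else rep(0, n)
      if (fortified && nm %in% spec$fortification_policy) {
        item_med <- item_med + doses[[nm]]
      }
      bind_cols(tibble(item_id = ids, nutrient = nm,
                       unit = units$unit[units$nutrient == nm]),
                triplet(item_med, spec$nutrient_dispersion))
    })
  }

  food_db(bind_rows(items), bind_rows(nutrients), bind_rows(footprints),
          bind_rows(prices), generate_recommendations(spec))
}

# Baseline per-capita supply masses, g/person/day; the canonical scenario
# table's BAU column. PBAs, legumes and soy foods are zero: national intake
# statistics do not record them separately.
default_bau_masses <- function() {
  tab <- load_canonical_scenarios()
  amounts <- tab$amount[tab$basis == "mass" & tab$scenario == "BAU"]
  setNames(amounts, tab$group[tab$basis == "mass" & tab$scenario == "BAU"])
}

#' Generate the baseline (BAU) supply profile
#'
#' Group totals default to the canonical baseline masses (Meats 190 g,
#' Eggs 30 g, Dairy 400 g, Seafood 30 g, ..., all PBA groups and Legumes
#' zero); the split across a group's items is random but fixed by the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param db The database the profile must cover.
#' @param group_totals Optional named numeric overriding the default
#'   g/person/day group totals.
#' @return A supply-stage, item-level diet profile tibble with columns
#'   `scenario`, `basis`, `stage`, `group`, `item_id`, `amount_g`.
#' @export
generate_bau_supply <- function(spec, db, group_totals = default_bau_masses()) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(db, "food_db"))
  assert_known_groups(names(group_totals), "group_totals")
  missing <- setdiff(names(group_totals), unique(db$items$group))
  if (length(missing) > 0) {
    abort(sprintf("database has no items for group(s): %s",
                  paste(missing, collapse = ", ")),
          class = "plantshift_coverage_error")
  }
  withr::with_seed(spec$seed + 1000003L, {
    items <- db$items |>
      filter(.data$group %in% names(group_totals)) |>
      select("item_id", "group") |>
      arrange(.data$group, .data$item_id)
    items |>
      group_by(.data$group) |>
      mutate(share = {
        w <- runif(dplyr::n())
        w / sum(w)
      }) |>
      ungroup() |>
      mutate(
        scenario = "BAU", basis = "mass", stage = "supply",
        amount_g = signif(.data$share * unname(group_totals[.data$group]), 9)
      ) |>
      select("scenario", "basis", "stage", "group", "item_id", "amount_g")
  })
}

#' Generate a recommendation table
#'
#' Daily thresholds in the style of Nordic-type recommendations for
#' moderately active healthy adults, with the most stringent sex-specific
#' value per nutrient (e.g. women's iron). Values are synthetic
#' placeholders, flagged as such in `source_note`, and can be overridden
#' per nutrient from a data frame or CSV file; unlisted nutrients keep
#' their defaults.
#'
#' @param spec A [synthetic_spec()] (unused randomness-wise; kept for a
#'   uniform generator interface).
#' @param overrides Optional data frame or CSV path with columns `nutrient`,
#'   `threshold` and optionally `direction`, `unit`, `source_note`.
#' @return A recommendation tibble.
#' @export
generate_recommendations <- function(spec = synthetic_spec(), overrides = NULL) {
  rec <- tibble::tribble(
    ~nutrient,       ~unit, ~threshold, ~direction,
    "protein",       "g",    58,   "minimum",
    "fibre",         "g",    35,   "minimum",
    "saturated_fat", "g",    22,   "limit",
    "pufa",          "g",    11,   "minimum",
    "sodium",        "mg",   2300, "limit",
    "iron",          "mg",   15,   "minimum",
    "zinc",          "mg",   9.6,  "minimum",
    "calcium",       "mg",   900,  "minimum",
    "magnesium",     "mg",   350,  "minimum",
    "phosphorus",    "mg",   600,  "minimum",
    "selenium",      "ug",   90,   "minimum",
    "folate",        "ug",   400,  "minimum",
    "b12",           "ug",   4,    "minimum",
    "vitamin_c",     "mg",   110,  "minimum",
    "vitamin_d",     "ug",   10,   "minimum",
    "vitamin_e",     "mg",   11,   "minimum"
  ) |>
    mutate(source_note = "synthetic placeholder (most stringent sex)")

  if (!is.null(overrides)) {
    if (is.character(overrides)) overrides <- read_table_file(overrides)
    overrides <- as_tibble(overrides)
    require_columns(overrides, "overrides", c("nutrient", "threshold"))
    for (j in seq_len(nrow(overrides))) {
      nm <- overrides$nutrient[j]
      hit <- rec$nutrient == nm
      if (!any(hit)) {
        rec <- bind_rows(rec, tibble(
          nutrient = nm,
          unit = if ("unit" %in% names(overrides)) overrides$unit[j] else NA_character_,
          threshold = overrides$threshold[j],
          direction = if ("direction" %in% names(overrides) &&
                          !is.na(overrides$direction[j])) {
            overrides$direction[j]
          } else "minimum",
          source_note = "user override"
        ))
      } else {
        rec$threshold[hit] <- overrides$threshold[j]
        if ("direction" %in% names(overrides) && !is.na(overrides$direction[j])) {
          rec$direction[hit] <- overrides$direction[j]
        }
        if ("unit" %in% names(overrides) && !is.na(overrides$unit[j])) {
          rec$unit[hit] <- overrides$unit[j]
        }
        rec$source_note[hit] <- "user override"
      }
    }
  }
  rec
}
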