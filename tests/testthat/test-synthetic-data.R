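test_that("generation is a pure function of the spec", {
  spec <- synthetic_spec(seed = 11)
  expect_identical(generate_database(spec), generate_database(spec))
  expect_false(identical(generate_database(spec),
                         generate_database(synthetic_spec(seed = 12))))
  db <- generate_database(spec)
  expect_identical(generate_bau_supply(spec, db),
                   generate_bau_supply(spec, db))
})

test_that("generated group medians respect the footprint ordering", {
  db <- default_db()
  med <- db$footprints |>
    dplyr::inner_join(dplyr::select(db$items, item_id, group),
                      by = "item_id") |>
    dplyr::group_by(indicator, group) |>
    dplyr::summarise(med = median(median), .groups = "drop")
  ghge <- function(g) med$med[med$indicator == "ghge" & med$group == g]
  expect_gt(ghge("Meats"), ghge("Plant-based Meat"))
  expect_gt(ghge("Plant-based Meat"), ghge("Legumes"))
  # ASF above its PBA counterpart for every indicator
  pairs <- dplyr::filter(food_group_table(), class == "pba",
                         group != "Plant-based Snacks")
  for (ind in unique(med$indicator)) {
    for (i in seq_len(nrow(pairs))) {
      asf <- med$med[med$indicator == ind & med$group == pairs$replaces[i]]
      pba <- med$med[med$indicator == ind & med$group == pairs$group[i]]
      expect_gt(asf, pba, label = paste(ind, pairs$replaces[i]))
    }
  }
})

test_that("fortification policy controls B12 and friends", {
  db <- default_db()
  fortified <- db$items$item_id[db$items$fortified_with != ""]
  expect_true(all(db$items$group[db$items$item_id %in% fortified] %in%
                    c("Plant-based Meat", "Plant-based Dairy",
                      "Plant-based Seafood")))
  b12 <- db$nutrients |>
    dplyr::filter(nutrient == "b12") |>
    dplyr::inner_join(dplyr::select(db$items, item_id, class, item_group = group),
                      by = "item_id")
  expect_true(all(b12$median[b12$item_id %in% fortified] > 0))
  plain_plant <- b12$class != "asf" & !b12$item_id %in% fortified
  expect_true(all(b12$median[plain_plant] == 0))

  none <- generate_database(synthetic_spec(seed = 101,
                                           fortification_policy = character()))
  b12n <- none$nutrients |>
    dplyr::filter(nutrient == "b12") |>
    dplyr::inner_join(dplyr::select(none$items, item_id, class), by = "item_id")
  expect_true(all(b12n$median[b12n$class != "asf"] == 0))
  expect_true(all(none$items$fortified_with == ""))
})

test_that("PBA sodium carries the uplift against the replaced group", {
  db <- default_db()
  na_med <- db$nutrients |>
    dplyr::filter(nutrient == "sodium") |>
    dplyr::inner_join(dplyr::select(db$items, item_id, group), by = "item_id") |>
    dplyr::group_by(group) |>
    dplyr::summarise(med = median(median), .groups = "drop")
  val <- function(g) na_med$med[na_med$group == g]
  expect_equal(val("Plant-based Meat"), 1.5 * val("Meats"))
  expect_equal(val("Plant-based Dairy"), 1.5 * val("Dairy"))
})

test_that("baseline supply matches the published group masses", {
  spec <- synthetic_spec(seed = 5)
  db <- generate_database(spec)
  bau <- generate_bau_supply(spec, db)
  g <- group_amounts(bau)
  amt <- function(grp) g$amount_g[g$group == grp]
  expect_equal(amt("Meats"), 190)
  expect_equal(amt("Eggs"), 30)
  expect_equal(amt("Dairy"), 400)
  expect_equal(amt("Seafood"), 30)
  expect_equal(amt("Plant-based Meat"), 0)
  expect_equal(amt("Legumes"), 0)
  expect_true(all(bau$stage == "supply"))

  one <- synthetic_spec(seed = 5, items_per_group = 1)
  db1 <- generate_database(one)
  bau1 <- generate_bau_supply(one, db1)
  expect_equal(bau1$amount_g[bau1$group == "Meats"], 190)

  db_missing <- db
  keep <- db$items$group != "Nuts"
  db_missing$items <- db$items[keep, ]
  expect_error(generate_bau_supply(spec, db_missing),
               class = "plantshift_coverage_error")
})

test_that("spec rejects an empty item count", {
  expect_error(synthetic_spec(items_per_group = 0),
               class = "plantshift_spec_error")
})

test_that("recommendation defaults cover the scored nutrients and merge overrides", {
  rec <- generate_recommendations()
  needed <- c("protein", "fibre", "iron", "zinc", "calcium", "magnesium",
              "phosphorus", "selenium", "folate", "b12", "vitamin_c",
              "vitamin_d", "vitamin_e", "pufa", "saturated_fat", "sodium")
  expect_true(all(needed %in% rec$nutrient))
  expect_equal(rec$direction[rec$nutrient == "sodium"], "limit")
  expect_equal(rec$direction[rec$nutrient == "saturated_fat"], "limit")
  expect_equal(rec$direction[rec$nutrient == "protein"], "minimum")
  expect_true(all(grepl("synthetic", rec$source_note)))

  over <- tibble::tibble(nutrient = c("iron", "histidine"),
                         threshold = c(9, 0.7),
                         unit = c(NA, "g"))
  rec2 <- generate_recommendations(overrides = over)
  expect_equal(rec2$threshold[rec2$nutrient == "iron"], 9)
  expect_equal(rec2$threshold[rec2$nutrient == "histidine"], 0.7)
  unchanged <- setdiff(rec$nutrient, "iron")
  expect_equal(rec2$threshold[match(unchanged, rec2$nutrient)],
               rec$threshold[match(unchanged, rec$nutrient)])
})
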