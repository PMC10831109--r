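test_that("a degenerate database collapses the sweep with a warning", {
  db <- simple_db()
  diet <- diet_profile(c(Meats = 100, Legumes = 200))
  expect_warning(cube <- quantile_sweep(diet, db), "degenerate")
  metrics <- setdiff(names(cube), c("scenario", "basis", "quantile"))
  for (m in metrics) {
    expect_equal(length(unique(cube[[m]])), 1, label = m)
  }
})

test_that("the sweep cube is monotone in the quantile and complete", {
  db <- default_db()
  bau <- default_bau()
  sc <- build_scenarios(bau, db, basis = "both")
  cube <- quantile_sweep(sc, db)
  expect_equal(nrow(cube), 7 * 2 * 3)
  for (m in c("ghge", "lu", "wu", "cost")) {
    wide <- tidyr::pivot_wider(cube[c("scenario", "basis", "quantile", m)],
                               names_from = "quantile", values_from = dplyr::all_of(m))
    expect_true(all(wide$q25 <= wide$median & wide$median <= wide$q75),
                label = m)
  }
  expect_equal(unique(cube$quantile), c("q25", "median", "q75"))
})

test_that("conscious consumer puts each group on its optimal item", {
  db <- default_db()
  bau <- default_bau()
  cc <- conscious_consumer(bau, db, objective = "min_cost")
  expect_equal(dplyr::arrange(group_amounts(cc), group)$amount_g,
               dplyr::arrange(group_amounts(bau), group)$amount_g)
  # chosen item is the cheapest in its group
  chosen <- dplyr::distinct(cc, group, item_id)
  prices <- dplyr::inner_join(db$prices,
                              dplyr::select(db$items, item_id, group),
                              by = "item_id")
  for (i in seq_len(nrow(chosen))) {
    in_group <- prices[prices$group == chosen$group[i], ]
    expect_equal(prices$median[prices$item_id == chosen$item_id[i]],
                 min(in_group$median))
  }
})

test_that("conscious-consumer footprints match exhaustive enumeration", {
  db <- default_db()  # 3 items per group
  bau <- default_bau()
  cc <- conscious_consumer(bau, db, objective = "min_ghge")
  cc_total <- unique(dplyr::filter(tidy(total_impact(cc, db)),
                                   indicator == "ghge")$total)
  # brute force: per group, try each item as the sole carrier
  g <- group_amounts(bau)
  fp <- dplyr::inner_join(
    dplyr::filter(db$footprints, indicator == "ghge"),
    dplyr::select(db$items, item_id, group), by = "item_id")
  best <- vapply(seq_len(nrow(g)), function(i) {
    kg <- g$amount_g[i] / 1000
    min(kg * fp$median[fp$group == g$group[i]])
  }, numeric(1))
  expect_equal(cc_total, sum(best))
  # any random within-group allocation is at least as impactful
  withr::with_seed(31, {
    for (rep in 1:5) {
      alloc <- db$items |>
        dplyr::select(item_id, group) |>
        dplyr::inner_join(g, by = "group") |>
        dplyr::group_by(group) |>
        dplyr::mutate(w = runif(dplyr::n()),
                      amount_g = amount_g * w / sum(w)) |>
        dplyr::ungroup() |>
        dplyr::transmute(scenario = "BAU", basis = "mass",
                         stage = "consumption", group, item_id, amount_g)
      total <- unique(dplyr::filter(tidy(total_impact(alloc, db)),
                                    indicator == "ghge")$total)
      expect_gte(total + 1e-9, cc_total)
    }
  })
})

test_that("single-item groups leave the conscious consumer indifferent", {
  spec <- synthetic_spec(seed = 8, items_per_group = 1)
  db <- generate_database(spec)
  bau <- apply_waste(generate_bau_supply(spec, db), db)
  cc <- conscious_consumer(bau, db, objective = "min_cost")
  expect_equal(dplyr::arrange(cc, group)$amount_g,
               dplyr::arrange(bau, group)$amount_g)
  expect_equal(dplyr::arrange(cc, group)$item_id,
               dplyr::arrange(bau, group)$item_id)
})

test_that("unknown conscious-consumer attributes are coverage errors", {
  db <- simple_db()
  expect_error(conscious_consumer(diet_profile(c(Meats = 10)), db,
                                  objective = "min_karma"),
               class = "plantshift_coverage_error")
  expect_error(conscious_consumer(diet_profile(c(Meats = 10)), db,
                                  objective = "sideways"),
               class = "plantshift_usage_error")
})

test_that("functional-unit comparison is a per-scenario ratio table", {
  db <- default_db()
  bau <- default_bau()
  im_mass <- impact_report(build_scenarios(bau, db, basis = "mass"), db)
  expect_equal(functional_unit_comparison(im_mass, im_mass)$ratio,
               rep(1, 7 * 3))

  im_energy <- impact_report(build_scenarios(bau, db, basis = "energy"), db)
  fu <- functional_unit_comparison(im_mass, im_energy)
  expect_equal(nrow(fu), 7 * 3)
  expect_equal(sort(unique(fu$scenario)), sort(names(default_scenarios())))
  expect_equal(fu$below_one, fu$ratio < 1)

  # closed form: one item, energy basis adds 25% more grams -> ratio 1.25
  m <- tibble::tibble(scenario = "TOY", indicator = "ghge", total = 4)
  e <- tibble::tibble(scenario = "TOY", indicator = "ghge", total = 5)
  expect_equal(functional_unit_comparison(m, e)$ratio, 1.25)

  expect_error(functional_unit_comparison(
    m, dplyr::mutate(e, scenario = "OTHER")),
    class = "plantshift_usage_error")
})

test_that("the full pipeline is deterministic and complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res1 <- suppressMessages(run_pipeline(
    pipeline_config(synthetic_spec(seed = 13), out_dir = d1)))
  res2 <- suppressMessages(run_pipeline(
    pipeline_config(synthetic_spec(seed = 13), out_dir = d2)))
  expect_identical(res1$manifest$config_hash, res2$manifest$config_hash)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # 7 scenarios x 2 bases, with adequacy, impact and expenditure per profile
  expect_equal(nrow(dplyr::distinct(res1$scenario_profiles, scenario, basis)),
               14)
  expect_setequal(
    intersect(c("adequacy", "impact_totals", "expenditure_totals"),
              names(res1)),
    c("adequacy", "impact_totals", "expenditure_totals"))
  expect_equal(nrow(dplyr::distinct(res1$adequacy, scenario, basis)), 14)
  # every output file is in the manifest with a checksum
  listed <- vapply(res1$manifest$files, `[[`, "", "file")
  expect_setequal(listed, setdiff(list.files(d1), "manifest.json"))

  d3 <- withr::local_tempdir()
  res3 <- suppressMessages(run_pipeline(
    pipeline_config(synthetic_spec(seed = 13), bases = "mass",
                    out_dir = d3)))
  expect_equal(unique(res3$scenario_profiles$basis), "mass")
  expect_false("functional_unit_comparison" %in% names(res3))
})
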