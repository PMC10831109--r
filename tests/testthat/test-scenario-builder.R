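test_that("waste adjustment scales supply into consumption", {
  db <- simple_db()
  supply <- diet_profile(c(Meats = 100, Legumes = 50), stage = "supply")
  cons <- apply_waste(supply, db)
  expect_equal(profile_amount(cons, "BAU", "Meats"), 80)  # 20% waste
  expect_equal(profile_amount(cons, "BAU", "Legumes"), 50)
  expect_true(all(cons$stage == "consumption"))

  expect_error(apply_waste(cons, db), class = "plantshift_usage_error")

  bad <- db
  bad$items$waste_fraction[1] <- 1
  expect_error(apply_waste(supply, bad), class = "plantshift_data_error")
})

test_that("consumption never exceeds supply for random profiles", {
  db <- default_db()
  withr::with_seed(99, {
    for (i in 1:10) {
      amounts <- setNames(runif(17, 0, 500), food_groups())
      supply <- diet_profile(amounts, stage = "supply")
      cons <- group_amounts(apply_waste(supply, db))
      expect_true(all(cons$amount_g <= amounts[cons$group] + 1e-12))
    }
  })
})

test_that("dietary energy is the density-weighted amount and is linear", {
  db <- simple_db()
  diet <- diet_profile(c(Meats = 100))
  expect_equal(sum(energy_of(diet, db)$kcal), 200)  # 100 g x 2.0 kcal/g

  # the published anchor: 190 g at 1.75 kcal/g
  db175 <- db
  db175$items$energy_density_kcal_g[1] <- 1.75
  expect_equal(sum(energy_of(diet_profile(c(Meats = 190)), db175)$kcal), 332.5)

  empty <- diet_profile(c(Meats = 0, Legumes = 0))
  expect_equal(sum(energy_of(empty, db)$kcal), 0)

  both <- diet_profile(c(Meats = 120, Legumes = 80))
  doubled <- diet_profile(c(Meats = 240, Legumes = 160))
  expect_equal(sum(energy_of(doubled, db)$kcal),
               2 * sum(energy_of(both, db)$kcal))
})

test_that("the flexitarian rule halves each replaced group exactly", {
  db <- default_db()
  bau <- canonical_bau()
  flx <- substitute_diet(bau, default_scenarios()$FLXPBA, db)
  expect_equal(profile_amount(flx, "FLXPBA", "Meats"), 95)
  expect_equal(profile_amount(flx, "FLXPBA", "Eggs"), 15)
  expect_equal(profile_amount(flx, "FLXPBA", "Seafood"), 15)
  expect_equal(profile_amount(flx, "FLXPBA", "Dairy"), 200)
  for (g in asf_groups()) {
    expect_equal(profile_amount(flx, "FLXPBA", g),
                 0.5 * profile_amount(bau, "BAU", g))
  }
})

test_that("vegan zeroes all ASF groups and vegetarian retains eggs and dairy", {
  db <- default_db()
  bau <- canonical_bau()
  vgn <- substitute_diet(bau, default_scenarios()$VGNPBA, db)
  for (g in asf_groups()) expect_equal(profile_amount(vgn, "VGNPBA", g), 0)
  vgt <- substitute_diet(bau, default_scenarios()$VGTPBA, db)
  expect_equal(profile_amount(vgt, "VGTPBA", "Eggs"), 30)
  expect_equal(profile_amount(vgt, "VGTPBA", "Dairy"), 400)
  expect_equal(profile_amount(vgt, "VGTPBA", "Meats"), 0)
  expect_equal(profile_amount(vgt, "VGTPBA", "Seafood"), 0)
})

test_that("the rule builder reproduces the unambiguous published PBA cells", {
  db <- default_db()
  bau <- canonical_bau()
  tab <- load_canonical_scenarios()
  for (scen in c("VGNPBA", "VGTPBA", "FLXPBA")) {
    built <- substitute_diet(bau, default_scenarios()[[scen]], db)
    for (g in c(asf_groups(), pba_groups(), "Snacks")) {
      expect_equal(profile_amount(built, scen, g),
                   canonical_cell(tab, scen, "mass", g),
                   label = paste(scen, g))
    }
  }
})

test_that("substitution conserves mass (mass basis) and energy (energy basis)", {
  db <- default_db()
  bau <- canonical_bau()
  # uncapped specs: PBA mode
  for (scen in c("VGNPBA", "VGTPBA", "FLXPBA")) {
    built <- substitute_diet(bau, default_scenarios()[[scen]], db)
    expect_equal(sum(group_amounts(built)$amount_g),
                 sum(group_amounts(bau)$amount_g), label = scen)
  }
  for (scen in c("VGNPBA", "VGTPBA", "FLXPBA")) {
    spec_e <- default_scenarios("energy")[[scen]]
    built <- substitute_diet(bau, spec_e, db)
    expect_equal(sum(energy_of(built, db)$kcal),
                 sum(energy_of(bau, db)$kcal),
                 tolerance = 1e-6, label = scen)
  }
  # whole-food mode without caps conserves mass too
  wf_uncapped <- scenario_spec("VGN_WF_UNCAPPED",
                               c("Meats", "Eggs", "Dairy", "Seafood"), 1,
                               "wf", wf_replacement_map(
                                 c("Meats", "Eggs", "Dairy", "Seafood")))
  built <- substitute_diet(bau, wf_uncapped, db)
  expect_equal(sum(group_amounts(built)$amount_g),
               sum(group_amounts(bau)$amount_g))
})

test_that("energy-basis replacement converts kilocalories to grams", {
  db <- simple_db()
  bau <- diet_profile(c(Meats = 100, Legumes = 0))
  spec <- scenario_spec("TOY", "Meats", 1, "wf",
                        list(Meats = tibble::tibble(target = "Legumes",
                                                    weight = 1)),
                        functional_unit = "energy")
  out <- substitute_diet(bau, spec, db)
  # 100 g x 2.0 kcal/g = 200 kcal; at 0.8 kcal/g that is 250 g
  expect_equal(profile_amount(out, "TOY", "Legumes"), 250)
  expect_equal(profile_amount(out, "TOY", "Meats"), 0)
})

test_that("caps overflow deterministically and infeasibility is an error", {
  db <- default_db()
  bau <- diet_profile(c(Meats = 100, Legumes = 0, Nuts = 0))
  two_targets <- list(Meats = tibble::tibble(
    target = c("Legumes", "Nuts"), weight = c(0.7, 0.3)))
  spec <- scenario_spec("CAPPED", "Meats", 1, "wf", two_targets,
                        caps = c(Legumes = 50))
  out <- substitute_diet(bau, spec, db)
  expect_equal(profile_amount(out, "CAPPED", "Legumes"), 50)
  expect_equal(profile_amount(out, "CAPPED", "Nuts"), 50)
  expect_equal(sum(group_amounts(out)$amount_g), 100)

  spec_bad <- scenario_spec("IMPOSSIBLE", "Meats", 1, "wf", two_targets,
                            caps = c(Legumes = 30, Nuts = 20))
  expect_error(substitute_diet(bau, spec_bad, db),
               class = "plantshift_infeasible_error")
})

test_that("the baseline passes through a mode-none scenario unchanged", {
  db <- default_db()
  bau <- canonical_bau()
  out <- substitute_diet(bau, default_scenarios()$BAU, db)
  expect_equal(group_amounts(out)$amount_g,
               group_amounts(dplyr::mutate(bau, scenario = "BAU"))$amount_g)
})

test_that("the canonical table loads with the published cells", {
  tab <- load_canonical_scenarios()
  expect_equal(nrow(tab), 17 * 7 * 2)
  for (g in asf_groups()) {
    expect_equal(canonical_cell(tab, "VGNPBA", "mass", g), 0)
  }
  expect_equal(canonical_cell(tab, "FLXWHOLE", "mass", "Legumes"), 100)
  expect_equal(canonical_cell(tab, "BAU", "mass", "Meats"), 190)
  expect_equal(canonical_cell(tab, "BAU", "energy", "Meats"), 333)

  # a single-scenario file yields one profile per basis
  wide <- readr::read_csv(system.file("extdata", "table1_scenarios.csv",
                                      package = "plantshift"),
                          show_col_types = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(wide[, c("group", "basis", "BAU")], f)
  profs <- canonical_profiles(load_canonical_scenarios(f), db = default_db())
  expect_equal(nrow(dplyr::distinct(profs, scenario, basis)), 2)

  # a missing cell is a parse error
  wide$BAU[3] <- NA
  readr::write_csv(wide, f)
  expect_error(load_canonical_scenarios(f), class = "plantshift_parse_error")
})
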