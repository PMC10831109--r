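#' Food-group taxonomy
#'
#' The analysis operates on 17 named food groups. Each group belongs to one
#' of three classes: `asf` (animal-source foods: meats, eggs, dairy,
#' seafood), `pba` (plant-based alternatives that mimic an animal product or
#' a conventional snack), and `wf` (whole plant foods and remaining
#' categories; `Other` bundles sugar products, salt, soft drinks, coffee and
#' juice). PBA groups carry a `replaces` pointer to the conventional group
#' they substitute for; this drives default replacement maps, sodium uplift
#' and fortification in the synthetic generator.
#'
#' @return A tibble with columns `group`, `class` and `replaces`.
#' @examples
#' food_group_table()
#' @export
food_group_table <- function() {
  tibble::tribble(
    ~group,                 ~class, ~replaces,
    "Meats",                "asf",  NA_character_,
    "Plant-based Meat",     "pba",  "Meats",
    "Eggs",                 "asf",  NA_character_,
    "Dairy",                "asf",  NA_character_,
    "Plant-based Dairy",    "pba",  "Dairy",
    "Seafood",              "asf",  NA_character_,
    "Plant-based Seafood",  "pba",  "Seafood",
    "Vegetables",           "wf",   NA_character_,
    "Fruits",               "wf",   NA_character_,
    "Potatoes",             "wf",   NA_character_,
    "Grains",               "wf",   NA_character_,
    "Plant fats",           "wf",   NA_character_,
    "Legumes",              "wf",   NA_character_,
    "Nuts",                 "wf",   NA_character_,
    "Snacks",               "wf",   NA_character_,
    "Plant-based Snacks",   "pba",  "Snacks",
    "Other",                "wf",   NA_character_
  )
}

#' @rdname food_group_table
#' @export
food_groups <- function() food_group_table()$group

#' @rdname food_group_table
#' @export
asf_groups <- function() {
  tab <- food_group_table()
  tab$group[tab$class == "asf"]
}

#' @rdname food_group_table
#' @export
pba_groups <- function() {
  tab <- food_group_table()
  tab$group[tab$class == "pba"]
}

#' @rdname food_group_table
#' @export
wf_groups <- function() {
  tab <- food_group_table()
  tab$group[tab$class == "wf"]
}

group_class <- function(groups) {
  tab <- food_group_table()
  tab$class[match(groups, tab$group)]
}

assert_known_groups <- function(groups, where = "input") {
  unknown <- setdiff(unique(groups), food_groups())
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown food group(s) in %s: %s", where,
      paste(unknown, collapse = ", ")
    ), class = "plantshift_mapping_error")
  }
  invisible(groups)
}
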