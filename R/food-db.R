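#' Construct a food database
#'
#' Bundles the five tables the pipeline consumes. All intensities are stored
#' per kilogram of food as purchased (1 litre of beverage is treated as
#' 1 kg), energy density in kcal per gram, and every uncertain quantity as a
#' `q25 <= median <= q75` triplet.
#'
#' @param items Tibble with columns `item_id`, `group`, `class`
#'   (`asf`/`pba`/`wf`), `energy_density_kcal_g`, `waste_fraction`,
#'   `fortified_with` (semicolon-separated nutrient names, `""` if none) and
#'   optionally `boundary_note` (system boundary of the footprint data).
#' @param nutrients Long tibble: `item_id`, `nutrient`, `unit` (amount per
#'   kg), `q25`, `median`, `q75`.
#' @param footprints Long tibble: `item_id`, `indicator` (`ghge`, `lu`,
#'   `wu`), `unit`, `q25`, `median`, `q75` (per kg).
#' @param prices Tibble: `item_id`, `currency`, `q25`, `median`, `q75`
#'   (currency per kg).
#' @param recommendations Tibble: `nutrient`, `unit`, `threshold` (amount
#'   per day), `direction` (`minimum` or `limit`), `source_note`. One row
#'   per nutrient; for minimum-type rows the threshold is the most stringent
#'   (largest) sex-specific recommendation.
#' @param validate Stop if [validate_database()] finds problems?
#' @return An object of class `food_db`.
#' @seealso [generate_database()], [read_food_database()]
#' @export
food_db <- function(items, nutrients, footprints, prices, recommendations,
                    validate = TRUE) {
  db <- structure(
    list(
      items = as_tibble(items),
      nutrients = as_tibble(nutrients),
      footprints = as_tibble(footprints),
      prices = as_tibble(prices),
      recommendations = as_tibble(recommendations)
    ),
    class = "food_db"
  )
  if (!"boundary_note" %in% names(db$items)) {
    db$items$boundary_note <- "cradle-to-consumer"
  }
  if (validate) {
    issues <- validate_database(db)
    if (nrow(issues) > 0) {
      abort(paste0(
        "food database failed validation:\n",
        paste(sprintf("- [%s] %s: %s", issues$rule, issues$item_id,
                      issues$message), collapse = "\n")
      ), class = "plantshift_validation_error")
    }
  }
  db
}

#' @export
print.food_db <- function(x, ...) {
  cat(sprintf(
    "<food_db> %d items in %d groups | %d nutrients | %d footprint indicators | %d recommendations\n",
    nrow(x$items), length(unique(x$items$group)),
    length(unique(x$nutrients$nutrient)),
    length(unique(x$footprints$indicator)),
    nrow(x$recommendations)
  ))
  invisible(x)
}

quantile_cols <- c("q25", "median", "q75")

issue_row <- function(rule, item_id, message) {
  tibble(rule = rule, item_id = as.character(item_id), message = message)
}

check_triplets <- function(tbl, label, key = tbl$item_id) {
  out <- list()
  bad_order <- which(!(tbl$q25 <= tbl$median & tbl$median <= tbl$q75))
  if (length(bad_order) > 0) {
    out <- c(out, list(issue_row(
      "quantile-order", key[bad_order],
      sprintf("%s: q25 <= median <= q75 violated", label)
    )))
  }
  neg <- which(tbl$q25 < 0 | tbl$median < 0 | tbl$q75 < 0)
  if (length(neg) > 0) {
    rule <- if (label == "price") "nonnegative-price" else "nonnegative-quantity"
    out <- c(out, list(issue_row(rule, key[neg],
                                 sprintf("%s: negative value", label))))
  }
  out
}

#' Validate a food database
#'
#' Checks every structural invariant the pipeline relies on and returns a
#' report instead of stopping, so callers can inspect all problems at once.
#' Rules: known groups, unique item ids, class consistent with the group
#' taxonomy, positive energy density, waste fraction in `[0, 1)`,
#' non-negative quantities with ordered quantile triplets, referential
#' integrity of the long tables, one recommendation row per nutrient with a
#' positive threshold and a valid direction.
#'
#' @param db A `food_db`.
#' @return Tibble with columns `rule`, `item_id`, `message`; zero rows for a
#'   conforming database.
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "food_db"))
  items <- db$items
  issues <- list()

  unknown <- setdiff(unique(items$group), food_groups())
  if (length(unknown) > 0) {
    bad <- items$item_id[items$group %in% unknown]
    issues <- c(issues, list(issue_row("unknown-group", bad,
                                       "group not in taxonomy")))
  }
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup) > 0) {
    issues <- c(issues, list(issue_row("unique-item-id", dup,
                                       "duplicated item id")))
  }
  expected <- group_class(items$group)
  bad_class <- which(!is.na(expected) & items$class != expected)
  if (length(bad_class) > 0) {
    issues <- c(issues, list(issue_row(
      "class-consistency", items$item_id[bad_class],
      "item class does not match its group's class"
    )))
  }
  bad_ed <- which(!(items$energy_density_kcal_g > 0))
  if (length(bad_ed) > 0) {
    issues <- c(issues, list(issue_row(
      "positive-energy-density", items$item_id[bad_ed],
      "energy density must be > 0"
    )))
  }
  bad_waste <- which(items$waste_fraction < 0 | items$waste_fraction >= 1)
  if (length(bad_waste) > 0) {
    issues <- c(issues, list(issue_row(
      "waste-fraction-range", items$item_id[bad_waste],
      "waste fraction must be in [0, 1)"
    )))
  }

  issues <- c(issues,
              check_triplets(db$nutrients, "nutrient"),
              check_triplets(db$footprints, "footprint"),
              check_triplets(db$prices, "price"))

  for (tbl_name in c("nutrients", "footprints", "prices")) {
    orphan <- setdiff(unique(db[[tbl_name]]$item_id), items$item_id)
    if (length(orphan) > 0) {
      issues <- c(issues, list(issue_row(
        "referential-integrity", orphan,
        sprintf("%s row references unknown item", tbl_name)
      )))
    }
  }

  rec <- db$recommendations
  dup_n <- rec$nutrient[duplicated(rec$nutrient)]
  if (length(dup_n) > 0) {
    issues <- c(issues, list(issue_row(
      "one-row-per-nutrient", dup_n,
      "recommendation table must hold one (most stringent) row per nutrient"
    )))
  }
  bad_thr <- which(!(rec$threshold > 0))
  if (length(bad_thr) > 0) {
    issues <- c(issues, list(issue_row(
      "positive-threshold", rec$nutrient[bad_thr],
      "recommendation threshold must be > 0"
    )))
  }
  bad_dir <- which(!rec$direction %in% c("minimum", "limit"))
  if (length(bad_dir) > 0) {
    issues <- c(issues, list(issue_row(
      "valid-direction", rec$nutrient[bad_dir],
      "direction must be 'minimum' or 'limit'"
    )))
  }

  if (length(issues) == 0) {
    tibble(rule = character(), item_id = character(), message = character())
  } else {
    bind_rows(issues)
  }
}

# value column lookup for a quantile name
pick_quantile <- function(tbl, quantile = c("median", "q25", "q75")) {
  quantile <- match.arg(quantile)
  tbl$value <- tbl[[quantile]]
  tbl
}
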