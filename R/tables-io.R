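#' Read and write food-database tables
#'
#' A database on disk is a directory (or named file set) of five delimited
#' tables: `items`, `nutrients`, `footprints`, `prices`,
#' `recommendations`. Comma or tab delimiters are sniffed from the first
#' line; files are UTF-8 with `.` decimal separator. Column names can be
#' remapped through a YAML config whose top level mirrors the table names,
#' e.g. `items: {Product: item_id, Category: group}`. Tables supplied with
#' only a `median` column get degenerate triplets (`q25 = median = q75`).
#'
#' @param path Directory containing `<table>.csv`/`.tsv`, or a named list of
#'   file paths with names `items`, `nutrients`, `footprints`, `prices`,
#'   `recommendations`.
#' @param config Optional path to a YAML column-mapping file, or an
#'   equivalent named list.
#' @param validate Stop on validation issues? (default `TRUE`).
#' @return A [food_db()].
#' @export
read_food_database <- function(path, config = NULL, validate = TRUE) {
  tables <- c("items", "nutrients", "footprints", "prices", "recommendations")
  if (is.character(path) && length(path) == 1 && dir.exists(path)) {
    files <- map(tables, function(tb) {
      hits <- list.files(path, pattern = paste0("^", tb, "\\.(csv|tsv|txt)$"),
                         full.names = TRUE)
      if (length(hits) == 0) {
        abort(sprintf("no file for table '%s' under %s", tb, path),
              class = "plantshift_io_error")
      }
      hits[[1]]
    })
    files <- setNames(files, tables)
  } else if (is.list(path) || (is.character(path) && !is.null(names(path)))) {
    files <- as.list(path)
    missing <- setdiff(tables, names(files))
    if (length(missing) > 0) {
      abort(sprintf("missing table file(s): %s",
                    paste(missing, collapse = ", ")),
            class = "plantshift_io_error")
    }
  } else {
    abort("`path` must be a directory or a named list of five table files",
          class = "plantshift_io_error")
  }

  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }

  raw <- imap(files[tables], function(f, tb) {
    tbl <- read_table_file(f)
    mapping <- config[[tb]]
    if (!is.null(mapping)) {
      # mapping: original name -> canonical name
      idx <- match(names(mapping), names(tbl))
      names(tbl)[idx[!is.na(idx)]] <- unlist(mapping)[!is.na(idx)]
    }
    tbl
  })

  raw$items <- require_columns(raw$items, "items",
    c("item_id", "group", "class", "energy_density_kcal_g",
      "waste_fraction", "fortified_with"))
  raw$items$fortified_with <- dplyr::coalesce(
    as.character(raw$items$fortified_with), "")
  raw$nutrients <- complete_triplet(require_columns(
    raw$nutrients, "nutrients", c("item_id", "nutrient", "unit", "median")))
  raw$footprints <- complete_triplet(require_columns(
    raw$footprints, "footprints", c("item_id", "indicator", "unit", "median")))
  raw$prices <- complete_triplet(require_columns(
    raw$prices, "prices", c("item_id", "currency", "median")))
  raw$recommendations <- require_columns(
    raw$recommendations, "recommendations",
    c("nutrient", "unit", "threshold", "direction"))
  if (!"source_note" %in% names(raw$recommendations)) {
    raw$recommendations$source_note <- ""
  }

  food_db(raw$items, raw$nutrients, raw$footprints, raw$prices,
          raw$recommendations, validate = validate)
}

read_table_file <- function(f) {
  if (!file.exists(f)) {
    abort(sprintf("file not found: %s", f), class = "plantshift_io_error")
  }
  first <- readLines(f, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(f, delim = delim, show_col_types = FALSE,
                    progress = FALSE, locale = readr::locale(decimal_mark = "."))
}

require_columns <- function(tbl, table_name, cols) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("table '%s' is missing required column(s): %s",
                  table_name, paste(missing, collapse = ", ")),
          class = "plantshift_schema_error")
  }
  tbl
}

# fill q25/q75 from median when absent (degenerate triplet)
complete_triplet <- function(tbl) {
  if (!"q25" %in% names(tbl)) tbl$q25 <- tbl$median
  if (!"q75" %in% names(tbl)) tbl$q75 <- tbl$median
  tbl
}

#' @rdname read_food_database
#' @param db A `food_db` to write.
#' @param dir Output directory (created if needed).
#' @export
write_food_database <- function(db, dir) {
  stopifnot(inherits(db, "food_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in names(db)) {
    readr::write_csv(db[[tb]], file.path(dir, paste0(tb, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Export a result table
#'
#' Serialises any result tibble to CSV or JSON with a deterministic column
#' order (as-is) and numbers at 6 significant digits, so repeated runs of
#' the same analysis produce byte-identical files.
#'
#' @param results A data frame (any pipeline result type).
#' @param path Output file; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  out <- as_tibble(results) |>
    mutate(across(where(is.numeric), ~ signif(.x, 6)))
  if (format == "csv") {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    jsonlite::write_json(out, path, digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}
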