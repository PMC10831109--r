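#' Configure an end-to-end run
#'
#' @param synthetic A [synthetic_spec()] used to generate the database and
#'   baseline when `db`/`bau` are not supplied.
#' @param db Optional pre-built [food_db()] (e.g. from
#'   [read_food_database()]).
#' @param bau Optional supply-stage baseline profile.
#' @param bases Functional units to run: subset of `c("mass", "energy")`.
#' @param quantiles Quantiles for the uncertainty sweep.
#' @param cost_method Expenditure aggregation, see [daily_expenditure()].
#' @param out_dir Output directory for [run_pipeline()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_spec(),
                            db = NULL, bau = NULL,
                            bases = c("mass", "energy"),
                            quantiles = c("q25", "median", "q75"),
                            cost_method = "group_quantile",
                            out_dir = tempfile("plantshift_run_")) {
  bases <- match.arg(bases, several.ok = TRUE)
  structure(
    list(synthetic = synthetic, db = db, bau = bau, bases = bases,
         quantiles = quantiles, cost_method = cost_method,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s': %s", stage, conditionMessage(e)),
          class = "plantshift_pipeline_error")
  })
}

#' Run the full analysis pipeline
#'
#' Generates (or takes) a food database and baseline supply, derives the
#' consumption-stage baseline, builds all scenarios under each requested
#' functional unit, and computes the adequacy, impact, expenditure,
#' quantile-sweep and functional-unit-comparison tables. Everything is
#' written to `config$out_dir` as CSV plus a JSON manifest listing the
#' seed, a config hash (output paths excluded, so runs are relocatable)
#' and an MD5 checksum per file; two runs with the same config are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with the database, the scenario
#'   profiles and every result table.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(stage) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))
  }

  log_stage("database")
  db <- pipeline_stage("database",
    config$db %||% generate_database(config$synthetic))
  log_stage("baseline")
  bau_supply <- pipeline_stage("baseline",
    config$bau %||% generate_bau_supply(config$synthetic, db))
  bau <- pipeline_stage("waste", apply_waste(bau_supply, db))

  log_stage("scenarios")
  profiles <- pipeline_stage("scenarios", {
    map_dfr(config$bases, function(b) {
      build_scenarios(bau, db, basis = b) |>
        allocate_items(db, shares = bau)
    })
  })

  log_stage("nutrition")
  adequacy <- pipeline_stage("nutrition", adequacy_report(profiles, db))
  log_stage("impact")
  impact <- pipeline_stage("impact", impact_report(profiles, db))
  contributions <- pipeline_stage("impact", total_impact(profiles, db))
  log_stage("expenditure")
  expenditure <- pipeline_stage("expenditure",
    expenditure_report(profiles, db, method = config$cost_method))
  exp_groups <- pipeline_stage("expenditure",
    daily_expenditure(profiles, db, method = config$cost_method))
  log_stage("sweep")
  sweep <- pipeline_stage("sweep",
    quantile_sweep(profiles, db, quantiles = config$quantiles,
                   cost_method = config$cost_method))
  fu <- NULL
  if (all(c("mass", "energy") %in% config$bases)) {
    fu <- pipeline_stage("functional-units", functional_unit_comparison(
      filter(impact, .data$basis == "mass"),
      filter(impact, .data$basis == "energy")))
  }

  log_stage("write")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list(
    scenario_profiles = profiles,
    adequacy = as_tibble(adequacy),
    impact_totals = as_tibble(impact),
    impact_contributions = as_tibble(contributions),
    expenditure_totals = as_tibble(expenditure),
    expenditure_groups = as_tibble(exp_groups),
    quantile_sweep = sweep
  )
  if (!is.null(fu)) outputs$functional_unit_comparison <- fu
  files <- imap(outputs, function(tbl, nm) {
    f <- file.path(config$out_dir, paste0(nm, ".csv"))
    write_results(tbl, f, format = "csv")
    f
  })

  manifest <- list(
    package = "plantshift",
    version = as.character(utils::packageVersion("plantshift")),
    seed = config$synthetic$seed,
    bases = config$bases,
    quantiles = config$quantiles,
    config_hash = config_hash(config),
    files = map(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(c(list(db = db, bau = bau, manifest = manifest), outputs))
}

# hash of the run configuration, excluding output paths so that runs are
# reproducible across working directories
config_hash <- function(config) {
  core <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(core), tmp)
  unname(tools::md5sum(tmp))
}
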