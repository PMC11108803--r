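#' Typed CSV readers and writers
#'
#' Each table the pipeline exchanges has a documented CSV schema; the
#' readers validate it (errors name the file, row and column), keep unknown
#' columns with a warning, and round-trip losslessly with the corresponding
#' writers (numbers are written with full precision).
#'
#' Schemas:
#' * transition table: `year` (optional), `sex`, `age`, `from_state`,
#'   `to_state`, `probability`
#' * population: `sex`, `age`, `state`, `count` (optional `year`)
#' * entrants: `year`, `sex`, `count`
#' * prevalence: `age_group`, `sex`, `year`, `prevalence`
#' * relative risks: `transition_type`, `age_group`, `sex`, `rr`
#'   (optional `log_rr_se`)
#' * mortality: `age_group`, `sex`, `cause`, `year`, `deaths`, `exposure`
#'
#' @name bamsim_io
NULL

read_schema_csv <- function(path, required, optional = character(),
                            checks = list()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column%s: %s", path,
                  if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra) > 0) {
    bamsim_warn(sprintf("%s: unknown column%s preserved: %s", path,
                        if (length(extra) > 1) "s" else "",
                        paste(extra, collapse = ", ")),
                class = "bamsim_unknown_columns")
  }
  for (col in names(checks)) {
    bad <- which(!checks[[col]](df[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("%s: invalid value in column '%s' at data row %d (value: %s)",
                    path, col, bad[1], format(df[[col]][bad[1]])))
    }
  }
  df
}

in_range <- function(lo, hi) function(x) is.finite(x) & x >= lo & x <= hi
is_sex <- function(x) x %in% SEXES

#' @rdname bamsim_io
#' @param path CSV file path.
#' @return The validated tibble.
#' @export
read_transition_table <- function(path) {
  read_schema_csv(path,
                  required = c("sex", "age", "from_state", "to_state", "probability"),
                  optional = "year",
                  checks = list(probability = in_range(0, 1),
                                age = in_range(0, 120), sex = is_sex))
}

#' @rdname bamsim_io
#' @export
read_population <- function(path) {
  read_schema_csv(path, required = c("sex", "age", "state", "count"),
                  optional = "year",
                  checks = list(count = function(x) is.finite(x) & x >= 0,
                                sex = is_sex))
}

#' @rdname bamsim_io
#' @export
read_entrants <- function(path) {
  read_schema_csv(path, required = c("year", "sex", "count"),
                  checks = list(count = function(x) is.finite(x) & x >= 0,
                                sex = is_sex))
}

#' @rdname bamsim_io
#' @export
read_prevalence <- function(path) {
  read_schema_csv(path, required = c("age_group", "sex", "year", "prevalence"),
                  checks = list(prevalence = in_range(0, 1), sex = is_sex))
}

#' @rdname bamsim_io
#' @export
read_rr_table <- function(path) {
  read_schema_csv(path, required = c("transition_type", "age_group", "sex", "rr"),
                  optional = "log_rr_se",
                  checks = list(rr = function(x) is.finite(x) & x > 0,
                                sex = is_sex))
}

#' @rdname bamsim_io
#' @export
read_mortality_series <- function(path) {
  read_schema_csv(path,
                  required = c("age_group", "sex", "cause", "year", "deaths", "exposure"),
                  checks = list(deaths = function(x) is.finite(x) & x >= 0,
                                exposure = function(x) is.finite(x) & x > 0,
                                sex = is_sex))
}

#' @rdname bamsim_io
#' @param x Table to write.
#' @export
write_bamsim_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a full input bundle from a directory of CSVs
#'
#' Expects `population.csv`, `transition_table.csv`, `prevalence.csv`,
#' `rr.csv`, `mortality.csv`, `entrants.csv` as written by
#' [write_input_bundle()].
#'
#' @param dir Directory path.
#' @return An input bundle list (with the default state space attached).
#' @export
read_input_bundle <- function(dir) {
  list(
    population = read_population(file.path(dir, "population.csv")),
    transition_table = read_transition_table(file.path(dir, "transition_table.csv")),
    prevalence = read_prevalence(file.path(dir, "prevalence.csv")),
    rr = read_rr_table(file.path(dir, "rr.csv")),
    mortality = read_mortality_series(file.path(dir, "mortality.csv")),
    entrants = read_entrants(file.path(dir, "entrants.csv")),
    state_space = default_state_space()
  )
}

#' Write a full input bundle to a directory of CSVs
#'
#' @param bundle An input bundle, e.g. from [generate_all()].
#' @param dir Directory path (created if needed).
#' @return `dir`, invisibly; also writes `manifest.json` with the seed and
#'   a hash of the generator configuration when the bundle carries one.
#' @export
write_input_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("population", "transition_table", "prevalence", "rr",
               "mortality", "entrants")) {
    write_bamsim_csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  manifest <- list(
    seed = bundle$config$seed,
    config_hash = if (!is.null(bundle$config)) rlang::hash(unclass(bundle$config)),
    files = paste0(c("population", "transition_table", "prevalence", "rr",
                     "mortality", "entrants"), ".csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write the tables of a scenario comparison
#'
#' Writes `outcomes_by_year.csv`, `differences_vs_baseline.csv`,
#' `life_years_gained.csv`, `life_expectancy.csv`, `composition.csv`,
#' `prevalence_scenarios.csv` and a JSON run summary (config hash, headline
#' values, logged events).
#'
#' @param res A `scenario_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(res, dir) {
  stopifnot(inherits(res, "scenario_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bamsim_csv(res$outcomes, file.path(dir, "outcomes_by_year.csv"))
  write_bamsim_csv(res$differences, file.path(dir, "differences_vs_baseline.csv"))
  write_bamsim_csv(res$life_years, file.path(dir, "life_years_gained.csv"))
  write_bamsim_csv(res$life_expectancy, file.path(dir, "life_expectancy.csv"))
  write_bamsim_csv(res$composition, file.path(dir, "composition.csv"))
  write_bamsim_csv(res$prevalence, file.path(dir, "prevalence_scenarios.csv"))
  headline <- comparison_cells(res) %>%
    filter(.data$sex == "all", .data$year == max(.data$year))
  summary <- list(
    config_hash = res$meta$config_hash,
    years = res$meta$years,
    scenarios = res$meta$scenarios,
    log = res$meta$log,
    headline = headline
  )
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
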