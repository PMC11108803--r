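#' Run the full scenario comparison
#'
#' Executes the whole pipeline: fit the mortality trend and convert it to
#' year-specific death-probability multipliers; fit the prevalence trend and
#' build each scenario's prevalence path; translate prevalence differences
#' into impact fractions and adjust the affected transition probabilities;
#' project every scenario; and compute outcome tables, cumulative
#' differences versus baseline, life-years gained and (healthy) life
#' expectancy at the index age. Deterministic given its inputs.
#'
#' @param inputs A named list with `population`, `transition_table`,
#'   `prevalence`, `rr`, `mortality`, `entrants` and optionally
#'   `state_space`, as produced by [generate_all()] or read from CSV.
#' @param scenarios Scenario labels to run; `"baseline"` is always run and
#'   is the comparator.
#' @param years Length-2 simulated calendar-year range.
#' @param mortality_window Year range of observed mortality used for the
#'   trend fit (default: all years present).
#' @param mortality_base_year Year anchoring the death-transition
#'   probabilities (default: the window end).
#' @param slope_multiplier Mortality-trend scenario multiplier (see
#'   [mortality_scenarios()]; default 1, the central projection).
#' @param mortality_fit Optional pre-computed [fit_loglinear_trend()] result
#'   used instead of fitting (the uncertainty module perturbs and injects
#'   fits this way).
#' @param since First year of cumulative differences (default 2015).
#' @param min_age Minimum age for the outcome measures (default 65).
#' @param report_years Years at which life expectancy is evaluated and
#'   uncertainty cells are reported (default `c(2020, 2040, 2060)` clipped
#'   to the simulated range).
#' @param target_year,reduction_fraction,interpolation,prevalence_floor
#'   Passed to [scenario_prevalence()].
#' @param healthy_states Passed to [healthy_life_expectancy_at_65()].
#' @param keep_trajectories Keep the full per-scenario trajectories on the
#'   result (default `FALSE`; they are large).
#' @return A `scenario_comparison`: list of tidy tibbles `outcomes`,
#'   `differences`, `life_years`, `life_expectancy`, `composition`,
#'   `prevalence`, plus `meta` (arguments, config hash and the pipeline's
#'   collected clipping/capping log) and optionally `trajectories`.
#' @export
run_comparison <- function(inputs,
                           scenarios = c("baseline", "constant", "optimistic"),
                           years = c(2006, 2060),
                           mortality_window = NULL,
                           mortality_base_year = NULL,
                           slope_multiplier = 1,
                           mortality_fit = NULL,
                           since = 2015,
                           min_age = 65,
                           report_years = c(2020, 2040, 2060),
                           target_year = 2060,
                           reduction_fraction = 0.5,
                           interpolation = c("loglinear", "linear"),
                           prevalence_floor = 1e-4,
                           healthy_states = NULL,
                           keep_trajectories = FALSE) {
  interpolation <- match.arg(interpolation)
  for (nm in c("population", "transition_table", "prevalence", "rr",
               "mortality", "entrants")) {
    if (is.null(inputs[[nm]])) abort(sprintf("inputs$%s is missing", nm))
  }
  ss <- inputs$state_space %||% default_state_space()
  scenarios <- union("baseline", scenarios)
  log_lines <- character()
  collect <- function(expr, stage) {
    withCallingHandlers(expr, bamsim_condition = function(w) {
      log_lines <<- c(log_lines, paste0(stage, ": ", conditionMessage(w)))
      rlang::cnd_muffle(w)
    })
  }
  fail_stage <- function(expr, stage) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }
  yrs <- seq(years[1], years[2])
  report_years <- intersect(report_years, yrs[yrs > years[1]])

  # 1. mortality trend -> year-specific death multipliers
  mfit <- mortality_fit %||%
    fail_stage(collect(fit_loglinear_trend(inputs$mortality, mortality_window),
                       "mortality_fit"), "mortality_fit")
  base_year <- mortality_base_year %||% attr(mfit, "reference_year")
  rates <- fail_stage(
    project_rates(mfit, horizon = years[2], slope_multiplier = slope_multiplier,
                  from = min(years[1], attr(mfit, "window")[1])),
    "mortality_projection")
  mult <- fail_stage(death_tp_multipliers(rates, base_year), "mortality_multipliers") %>%
    filter(.data$year %in% yrs)
  tt_y <- fail_stage(collect(apply_death_multipliers(inputs$transition_table, mult, ss),
                             "mortality_scaling"), "mortality_scaling")

  # 2. prevalence trend and scenario paths
  pfit <- fail_stage(fit_prevalence_trend(inputs$prevalence), "prevalence_fit")
  prev_paths <- purrr::map(
    setNames(scenarios, scenarios),
    ~fail_stage(collect(
      scenario_prevalence(pfit, inputs$prevalence, .x, horizon = years[2],
                          target_year = target_year,
                          reduction_fraction = reduction_fraction,
                          floor = prevalence_floor,
                          interpolation = interpolation),
      paste0("prevalence_", .x)), paste0("prevalence_", .x)))

  # 3. impact fractions and per-scenario projection
  map <- affected_transition_map(ss)
  trajs <- purrr::imap(prev_paths, function(prev, label) {
    tt_s <- if (label == "baseline") {
      tt_y
    } else {
      deltas <- fail_stage(
        delta_parf_table(prev_paths$baseline, prev, inputs$rr) %>%
          filter(.data$year %in% yrs),
        paste0("delta_parf_", label))
      fail_stage(collect(apply_delta_parf(tt_y, deltas, map, ss),
                         paste0("adjust_", label)), paste0("adjust_", label))
    }
    fail_stage(project(inputs$population, tt_s, inputs$entrants, years, ss),
               paste0("project_", label))
  })

  # 4. outcomes
  outcomes <- purrr::imap(trajs, ~outcome_table(.x, .y, min_age)) %>% bind_rows()
  cf_labels <- setdiff(scenarios, "baseline")
  differences <- purrr::map(setNames(cf_labels, cf_labels), function(label) {
    scenario_difference(trajs[[label]], trajs$baseline, since, min_age) %>%
      mutate(scenario = label, .before = 1)
  }) %>% bind_rows()
  life_years <- purrr::map(setNames(cf_labels, cf_labels), function(label) {
    life_years_gained(trajs[[label]], trajs$baseline, since, min_age) %>%
      mutate(scenario = label, .before = 1)
  }) %>% bind_rows()
  life_expectancy <- purrr::imap(trajs, function(traj, label) {
    life_expectancy_table(traj, report_years, min_age, healthy_states) %>%
      mutate(scenario = label, .before = 1)
  }) %>% bind_rows()
  composition <- purrr::imap(trajs, function(traj, label) {
    life_year_composition(traj, min_age) %>%
      filter(.data$year %in% report_years) %>%
      mutate(scenario = label, .before = 1)
  }) %>% bind_rows()

  args <- list(scenarios = scenarios, years = years,
               mortality_window = attr(mfit, "window"),
               mortality_base_year = base_year,
               slope_multiplier = slope_multiplier, since = since,
               min_age = min_age, report_years = report_years,
               target_year = target_year, reduction_fraction = reduction_fraction,
               interpolation = interpolation, prevalence_floor = prevalence_floor,
               healthy_states = healthy_states)
  res <- list(
    outcomes = outcomes,
    differences = differences,
    life_years = life_years,
    life_expectancy = life_expectancy,
    composition = composition,
    prevalence = bind_rows(prev_paths),
    meta = c(args, list(
      config_hash = rlang::hash(list(inputs, args)),
      log = log_lines))
  )
  if (keep_trajectories) res$trajectories <- trajs
  structure(res, class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> scenarios: %s; years %d-%d\n",
              paste(x$meta$scenarios, collapse = ", "),
              x$meta$years[1], x$meta$years[2]))
  final <- x$differences %>%
    filter(.data$year == max(.data$year), .data$sex == "all",
           .data$measure == "deaths")
  if (nrow(final) > 0) {
    cat(sprintf("cumulative deaths avoided vs baseline by %d (all, since %d):\n",
                max(x$differences$year), x$meta$since))
    for (i in seq_len(nrow(final))) {
      cat(sprintf("  %-10s %12.0f (%+.1f per 100 000)\n", final$scenario[i],
                  final$avoided[i], final$avoided_per_100k[i]))
    }
  }
  if (length(x$meta$log) > 0) {
    cat(sprintf("%d logged adjustment events (see $meta$log)\n", length(x$meta$log)))
  }
  invisible(x)
}

#' Tidy cell view of a scenario comparison
#'
#' Flattens the headline outputs (cumulative differences, life-years gained
#' and life expectancy at the reporting years) into one
#' `(table, scenario, year, sex, measure, value)` tibble -- the unit the
#' uncertainty module summarises over Monte Carlo draws.
#'
#' @param x A `scenario_comparison`.
#' @return A tibble with one row per reported cell.
#' @export
comparison_cells <- function(x) {
  stopifnot(inherits(x, "scenario_comparison"))
  ry <- x$meta$report_years
  bind_rows(
    x$differences %>%
      filter(.data$year %in% ry) %>%
      tidyr::pivot_longer(c("avoided", "avoided_per_100k"),
                          names_to = "kind", values_to = "value") %>%
      mutate(measure = paste0(.data$measure, "_", .data$kind)) %>%
      select("scenario", "year", "sex", "measure", "value") %>%
      mutate(table = "differences", .before = 1),
    x$life_years %>%
      filter(.data$year %in% ry) %>%
      mutate(table = "life_years", measure = "life_years_gained") %>%
      select("table", "scenario", "year", "sex", "measure", value = "life_years_gained"),
    x$life_expectancy %>%
      tidyr::pivot_longer(c("le", "hle"), names_to = "measure", values_to = "value") %>%
      mutate(table = "life_expectancy") %>%
      select("table", "scenario", "year", "sex", "measure", "value")
  ) %>%
    arrange(.data$table, .data$scenario, .data$year, .data$sex, .data$measure)
}

#' @export
tidy.scenario_comparison <- function(x, ...) comparison_cells(x)

#' @export
glance.scenario_comparison <- function(x, ...) {
  tibble(
    n_scenarios = length(x$meta$scenarios),
    year_start = x$meta$years[1], year_end = x$meta$years[2],
    since = x$meta$since, min_age = x$meta$min_age,
    n_logged_events = length(x$meta$log),
    config_hash = x$meta$config_hash
  )
}
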