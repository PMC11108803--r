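#' Outcome measures from a projected trajectory
#'
#' Incident cases, deaths, person-years, scenario differences, and period
#' (healthy) life expectancy at 65, computed from the flows and populations
#' of a `population_trajectory`.
#'
#' @name outcomes
NULL

# alive person-years per (year, sex), mid-year approximation:
# average of start-of-year and start-of-next-year counts at ages >= min_age
person_years <- function(traj, min_age = 65, by_state = FALSE) {
  ss <- attr(traj, "state_space")
  alive_states <- states_of(ss, alive_only = TRUE)
  keys <- c("year", "sex", if (by_state) "state")
  pop <- traj$population %>%
    filter(.data$state %in% alive_states, .data$age >= min_age) %>%
    group_by(across(all_of(keys))) %>%
    summarise(n = sum(.data$count), .groups = "drop")
  nxt <- pop %>% mutate(year = .data$year - 1L) %>% rename(n_end = "n")
  pop %>%
    inner_join(nxt, by = keys) %>%
    mutate(person_years = (.data$n + .data$n_end) / 2) %>%
    select(all_of(keys), "person_years")
}

#' Incident cases of dementia or disability
#'
#' Sums the annual flows from states lacking the condition into states having
#' it, among persons aged at least `min_age` at the transition. A move from
#' disability into dementia counts as a dementia incident but not a
#' disability incident.
#'
#' @param traj A `population_trajectory` with flows.
#' @param condition `"dementia"` or `"disability"`.
#' @param min_age Minimum age at transition (default 65).
#' @return A tibble `year`, `sex`, `cases`.
#' @export
incident_cases <- function(traj, condition = c("dementia", "disability"), min_age = 65) {
  condition <- rlang::arg_match(condition)
  ss <- attr(traj, "state_space")
  flag <- switch(condition, dementia = "is_dementia", disability = "has_disability")
  has <- ss$states$state[ss$states[[flag]] & !ss$states$is_death]
  lacks <- ss$states$state[!ss$states[[flag]] & !ss$states$is_death]
  traj$flows %>%
    filter(.data$from_state %in% lacks, .data$to_state %in% has,
           .data$age >= min_age) %>%
    group_by(.data$year, .data$sex) %>%
    summarise(cases = sum(.data$count), .groups = "drop") %>%
    tidyr::complete(year = traj$years, sex = unique(traj$flows$sex),
                    fill = list(cases = 0))
}

#' Deaths per year
#'
#' @inheritParams incident_cases
#' @return A tibble `year`, `sex`, `deaths` of flows into the death states
#'   among persons aged at least `min_age`.
#' @export
death_counts <- function(traj, min_age = 65) {
  ss <- attr(traj, "state_space")
  dead <- states_of(ss)[ss$states$is_death]
  traj$flows %>%
    filter(.data$to_state %in% dead, .data$age >= min_age) %>%
    group_by(.data$year, .data$sex) %>%
    summarise(deaths = sum(.data$count), .groups = "drop") %>%
    tidyr::complete(year = traj$years, sex = unique(traj$flows$sex),
                    fill = list(deaths = 0))
}

#' Annual outcome table for one scenario
#'
#' Incident disability and dementia cases, deaths, alive person-years and
#' rates per 1000 person-years among the population aged `min_age` and over,
#' per year and sex, with a both-sex total (`sex = "all"`).
#'
#' @inheritParams incident_cases
#' @param scenario Label attached to the rows.
#' @return A tidy tibble `scenario`, `year`, `sex`, `measure`, `value` with
#'   measures `disability_incidence`, `dementia_incidence`, `deaths`,
#'   `person_years`, and the corresponding `*_rate_per_1000`.
#' @export
outcome_table <- function(traj, scenario = "baseline", min_age = 65) {
  wide <- incident_cases(traj, "disability", min_age) %>%
    rename(disability_incidence = "cases") %>%
    left_join(incident_cases(traj, "dementia", min_age) %>%
                rename(dementia_incidence = "cases"), by = c("year", "sex")) %>%
    left_join(death_counts(traj, min_age) %>% rename(deaths = "deaths"),
              by = c("year", "sex")) %>%
    left_join(person_years(traj, min_age), by = c("year", "sex"))
  both <- wide %>%
    group_by(.data$year) %>%
    summarise(across(c("disability_incidence", "dementia_incidence", "deaths",
                       "person_years"), sum), .groups = "drop") %>%
    mutate(sex = "all")
  bind_rows(wide, both) %>%
    mutate(
      disability_incidence_rate_per_1000 = 1000 * .data$disability_incidence / .data$person_years,
      dementia_incidence_rate_per_1000 = 1000 * .data$dementia_incidence / .data$person_years,
      death_rate_per_1000 = 1000 * .data$deaths / .data$person_years
    ) %>%
    tidyr::pivot_longer(-c("year", "sex"), names_to = "measure", values_to = "value") %>%
    mutate(scenario = scenario, .before = 1) %>%
    arrange(.data$year, .data$sex, .data$measure)
}

#' Cumulative avoided burden of a counterfactual versus baseline
#'
#' For deaths and incident dementia/disability cases: cumulative
#' `baseline - counterfactual` from `since` onwards, so positive values are
#' burden avoided and negative values additional burden. The per-100 000
#' figures divide by the baseline scenario's cumulative alive person-years
#' aged `min_age` and over, over the same window.
#'
#' @param counterfactual,baseline `population_trajectory` objects sharing
#'   years and strata.
#' @param since First year of accumulation (default 2015).
#' @param min_age Minimum age (default 65).
#' @return A tibble `year`, `sex`, `measure`, `avoided`, `avoided_per_100k`,
#'   `cumulative_person_years`.
#' @export
scenario_difference <- function(counterfactual, baseline, since = 2015, min_age = 65) {
  if (!identical(counterfactual$years, baseline$years)) {
    abort("counterfactual and baseline trajectories cover different year ranges")
  }
  counts <- function(traj) {
    bind_rows(
      death_counts(traj, min_age) %>% mutate(measure = "deaths") %>% rename(n = "deaths"),
      incident_cases(traj, "dementia", min_age) %>% mutate(measure = "dementia_cases") %>% rename(n = "cases"),
      incident_cases(traj, "disability", min_age) %>% mutate(measure = "disability_cases") %>% rename(n = "cases")
    )
  }
  both_sexes <- function(d) {
    bind_rows(d, d %>% group_by(.data$year, .data$measure) %>%
                summarise(n = sum(.data$n), .groups = "drop") %>% mutate(sex = "all"))
  }
  cf <- both_sexes(counts(counterfactual)) %>% rename(n_cf = "n")
  bl <- both_sexes(counts(baseline)) %>% rename(n_bl = "n")

  py <- person_years(baseline, min_age)
  py <- bind_rows(py, py %>% group_by(.data$year) %>%
                    summarise(person_years = sum(.data$person_years), .groups = "drop") %>%
                    mutate(sex = "all")) %>%
    filter(.data$year >= since) %>%
    group_by(.data$sex) %>%
    arrange(.data$year, .by_group = TRUE) %>%
    mutate(cumulative_person_years = cumsum(.data$person_years)) %>%
    ungroup() %>%
    select("year", "sex", "cumulative_person_years")

  inner_join(bl, cf, by = c("year", "sex", "measure")) %>%
    filter(.data$year >= since) %>%
    group_by(.data$sex, .data$measure) %>%
    arrange(.data$year, .by_group = TRUE) %>%
    mutate(avoided = cumsum(.data$n_bl - .data$n_cf)) %>%
    ungroup() %>%
    left_join(py, by = c("year", "sex")) %>%
    mutate(avoided_per_100k = 1e5 * .data$avoided / .data$cumulative_person_years) %>%
    select("year", "sex", "measure", "avoided", "avoided_per_100k",
           "cumulative_person_years") %>%
    arrange(.data$year, .data$sex, .data$measure)
}

#' Cumulative life-years gained versus baseline
#'
#' Cumulative difference in alive person-years aged `min_age` and over
#' (counterfactual minus baseline), running from `since`.
#'
#' @inheritParams scenario_difference
#' @return A tibble `year`, `sex` (including `"all"`), `life_years_gained`.
#' @export
life_years_gained <- function(counterfactual, baseline, since = 2015, min_age = 65) {
  if (!identical(counterfactual$years, baseline$years)) {
    abort("counterfactual and baseline trajectories cover different year ranges")
  }
  py <- function(traj, label) {
    d <- person_years(traj, min_age)
    bind_rows(d, d %>% group_by(.data$year) %>%
                summarise(person_years = sum(.data$person_years), .groups = "drop") %>%
                mutate(sex = "all")) %>%
      rename(!!label := "person_years")
  }
  inner_join(py(counterfactual, "py_cf"), py(baseline, "py_bl"),
             by = c("year", "sex")) %>%
    filter(.data$year >= since) %>%
    group_by(.data$sex) %>%
    arrange(.data$year, .by_group = TRUE) %>%
    mutate(life_years_gained = cumsum(.data$py_cf - .data$py_bl)) %>%
    ungroup() %>%
    select("year", "sex", "life_years_gained")
}

# --- period life table ------------------------------------------------------

# model-implied life table for one calendar year from age min_age up;
# sex "both" pools deaths and populations across sexes
model_life_table <- function(traj, year, sex = "both", min_age = 65,
                             healthy_states = NULL) {
  ss <- attr(traj, "state_space")
  alive_states <- states_of(ss, alive_only = TRUE)
  dead_states <- states_of(ss)[ss$states$is_death]
  healthy_states <- healthy_states %||% with(
    ss$states, state[!is_death & !has_cvd & !is_dementia & !has_disability])
  sexes <- if (identical(sex, "both")) SEXES else sex
  if (!year %in% traj$years) abort(sprintf("year %d is not covered by the trajectory", year))

  pop <- traj$population %>%
    filter(.data$year == !!year, .data$sex %in% sexes,
           .data$state %in% alive_states, .data$age >= min_age)
  at_risk <- pop %>% group_by(.data$age) %>%
    summarise(n = sum(.data$count), .groups = "drop")
  healthy <- pop %>%
    filter(.data$state %in% healthy_states) %>%
    group_by(.data$age) %>%
    summarise(n_healthy = sum(.data$count), .groups = "drop")
  deaths <- traj$flows %>%
    filter(.data$year == !!year, .data$sex %in% sexes,
           .data$to_state %in% dead_states, .data$age >= min_age) %>%
    group_by(.data$age) %>%
    summarise(d = sum(.data$count), .groups = "drop")

  lt <- tibble(age = seq(min_age, max(traj$ages))) %>%
    left_join(at_risk, by = "age") %>%
    left_join(deaths, by = "age") %>%
    left_join(healthy, by = "age") %>%
    mutate(across(c("n", "d", "n_healthy"), ~tidyr::replace_na(.x, 0)),
           q = if_else(.data$n > 0, .data$d / .data$n, 0),
           healthy_frac = if_else(.data$n > 0, .data$n_healthy / .data$n, 0))

  top <- nrow(lt)
  if (lt$q[top] <= 0) {
    abort("death probability at the top age is zero: the open-ended top interval is undefined")
  }
  l <- numeric(top)
  l[1] <- 1
  for (i in seq_len(top - 1)) l[i + 1] <- l[i] * (1 - lt$q[i])
  # half-cycle correction below the top age; open top interval lives l/q
  L <- l * (1 - lt$q / 2)
  L[top] <- l[top] / lt$q[top]
  lt %>% mutate(l = l, L = L)
}

#' Period life expectancy at an index age
#'
#' Builds a period life table from the model's age-specific death
#' probabilities in one calendar year (`q(a)` = deaths during the year over
#' population at risk at its start), with survivorship `l(65) = 1`, a
#' half-cycle correction `L(a) = l(a)(1 - q(a)/2)`, and an open-ended top
#' age interval contributing `l(top)/q(top)` person-years.
#'
#' @param traj A `population_trajectory`.
#' @param year Calendar year.
#' @param sex `"both"` (pooled death probabilities), `"men"` or `"women"`.
#' @param min_age Index age (default 65).
#' @return Remaining life expectancy in years.
#' @export
life_expectancy_at_65 <- function(traj, year, sex = "both", min_age = 65) {
  sum(model_life_table(traj, year, sex, min_age)$L)
}

#' Sullivan healthy life expectancy at an index age
#'
#' Weights each age's life-table person-years by the fraction of that age's
#' alive population occupying a healthy state. By default healthy means no
#' CVD, no dementia and no disability, so cognitive impairment alone does
#' not end healthy life; supply `healthy_states` to change the definition.
#'
#' @inheritParams life_expectancy_at_65
#' @param healthy_states Character vector of state identifiers counted as
#'   healthy; default derives them from the state flags.
#' @return Healthy life expectancy in years (at most the corresponding
#'   [life_expectancy_at_65()]).
#' @export
healthy_life_expectancy_at_65 <- function(traj, year, sex = "both", min_age = 65,
                                          healthy_states = NULL) {
  lt <- model_life_table(traj, year, sex, min_age, healthy_states)
  sum(lt$L * lt$healthy_frac)
}

#' Life expectancy table over years and sexes
#'
#' Convenience wrapper evaluating total and healthy life expectancy at the
#' index age for several calendar years, for both sexes pooled and each sex.
#'
#' @inheritParams healthy_life_expectancy_at_65
#' @param years Calendar years to evaluate.
#' @return A tibble `year`, `sex`, `le`, `hle`.
#' @export
life_expectancy_table <- function(traj, years, min_age = 65, healthy_states = NULL) {
  tidyr::expand_grid(year = years, sex = c("all", SEXES)) %>%
    mutate(purrr::map2_dfr(.data$year, .data$sex, function(y, s) {
      s2 <- if (s == "all") "both" else s
      lt <- model_life_table(traj, y, s2, min_age, healthy_states)
      tibble(le = sum(lt$L), hle = sum(lt$L * lt$healthy_frac))
    }))
}

#' Composition of alive person-years by health category
#'
#' Partitions alive person-years aged `min_age` and over into four mutually
#' exclusive categories -- dementia (cognitive impairment with disability),
#' disability without dementia, CVD without disability or dementia, and
#' healthy -- as percentages summing to 100 per year.
#'
#' @inheritParams incident_cases
#' @return A tibble `year`, `category`, `percent`.
#' @export
life_year_composition <- function(traj, min_age = 65) {
  ss <- attr(traj, "state_space")
  cat_of <- ss$states %>%
    filter(!.data$is_death) %>%
    mutate(category = dplyr::case_when(
      .data$is_dementia ~ "dementia",
      .data$has_disability ~ "disability",
      .data$has_cvd ~ "cvd",
      TRUE ~ "healthy"
    )) %>%
    select("state", "category")
  person_years(traj, min_age, by_state = TRUE) %>%
    left_join(cat_of, by = "state") %>%
    group_by(.data$year, .data$category) %>%
    summarise(py = sum(.data$person_years), .groups = "drop") %>%
    group_by(.data$year) %>%
    mutate(percent = 100 * .data$py / sum(.data$py)) %>%
    ungroup() %>%
    tidyr::complete(year = unique(.data$year),
                    category = c("healthy", "cvd", "disability", "dementia"),
                    fill = list(py = 0, percent = 0)) %>%
    select("year", "category", "percent")
}
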