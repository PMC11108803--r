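#' A hand-checkable miniature input bundle
#'
#' Three 5-year age groups (ages 65-79), two sexes, a five-year simulation
#' (2013-17), flat round-number transition probabilities, exactly log-linear
#' observed prevalence (2010-13) and noiseless observed mortality (2010-13):
#' every number the pipeline produces from this bundle can be verified by
#' manual arithmetic, and the full-pipeline output is frozen as a golden
#' regression fixture in the test suite. Entirely deterministic (no random
#' numbers).
#'
#' @return A list with the input bundle fields of [generate_all()] plus
#'   `run_args`, the [run_comparison()] arguments that define the miniature
#'   run (years 2013-17, differences cumulative since 2014, optimistic
#'   target year 2017).
#' @export
generate_toy_example <- function() {
  ss <- default_state_space()
  ages <- 65:79
  groups <- c("65-69", "70-74", "75-79")

  population <- tidyr::expand_grid(sex = SEXES, age = ages) %>%
    tidyr::expand_grid(tibble(state = c("FREE", "CI", "DIS"),
                              count = c(8000, 1000, 1000))) %>%
    select("sex", "age", "state", "count")

  map <- affected_transition_map(ss)
  base_p <- c(cvd_incidence = 0.02, ci_incidence = 0.02,
              disability_incidence = 0.02, disability_recovery = 0.10,
              cvd_death = 0.01, noncvd_death = 0.02)
  tt <- tidyr::expand_grid(sex = SEXES, age = ages, map) %>%
    mutate(probability = unname(base_p[.data$transition_type])) %>%
    select("sex", "age", "from_state", "to_state", "probability") %>%
    complete_stay_probability(ss)

  prevalence <- tidyr::expand_grid(age_group = groups, sex = SEXES, year = 2010:2013) %>%
    mutate(p0 = 0.40 * if_else(.data$sex == "men", 1, 0.9),
           prevalence = .data$p0 * exp(-0.05 * (.data$year - 2010))) %>%
    select("age_group", "sex", "year", "prevalence")

  rr_vals <- c(cvd_incidence = 1.5, ci_incidence = 1.25,
               disability_incidence = 1.25, disability_recovery = 0.8,
               cvd_death = 1.8, noncvd_death = 1.1)
  rr <- tidyr::expand_grid(transition_type = names(rr_vals),
                           age_group = groups, sex = SEXES) %>%
    mutate(rr = unname(rr_vals[.data$transition_type]), log_rr_se = 0.05)

  mortality <- tidyr::expand_grid(age_group = groups, sex = SEXES,
                                  cause = c("CVD", "non-CVD"), year = 2010:2013) %>%
    mutate(rate = if_else(.data$cause == "CVD",
                          0.010 * exp(-0.02 * (.data$year - 2013)),
                          0.020 * exp(-0.01 * (.data$year - 2013))),
           exposure = 1e5,
           deaths = .data$rate * .data$exposure) %>%
    select("age_group", "sex", "cause", "year", "deaths", "exposure")

  entrants <- tidyr::expand_grid(year = 2013:2017, sex = SEXES) %>%
    mutate(count = 100)

  list(
    population = population, transition_table = tt, prevalence = prevalence,
    rr = rr, mortality = mortality, entrants = entrants, state_space = ss,
    run_args = list(years = c(2013, 2017), since = 2014, min_age = 65,
                    report_years = c(2015, 2017), target_year = 2017,
                    reduction_fraction = 0.5)
  )
}
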