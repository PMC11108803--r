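#' Synthetic input bundles
#'
#' The pipeline is calibrated, in production use, to survey and registry
#' inputs: a base-year population by age, sex and health state; one-year
#' transition probabilities; hypertension prevalence by survey year with a
#' declining log-scale trend; adjusted relative risks per affected
#' transition; and cause-specific death counts with a log-linear decline.
#' None of those sources are redistributable, so this module generates
#' synthetic stand-ins with the same statistical structure and
#' national-scale magnitudes, making every stage of the pipeline runnable
#' and testable without downloads.
#'
#' @name synthetic_data
NULL

#' Configuration for the synthetic generator
#'
#' Defaults describe a national-scale population (60 million persons across
#' all ages at the base year, of whom the modelled ages 35-100 are a share
#' determined by a piecewise-linear age density), hypertension prevalence
#' observed 2003-17 declining about 0.8% per year on the log scale (a
#' decline, but shallower than a halving spread over 2017-60, so the three
#' futures genuinely diverge),
#' cause-specific mortality observed 2007-16 declining 2.5% (CVD) and 1.2%
#' (non-CVD) per year, relative risks above one for incidence and death
#' transitions and below one for disability recovery, and transition
#' probabilities increasing with age on logistic-in-age curves.
#'
#' @param seed Integer seed controlling all generator randomness.
#' @param base_year First simulated year (default 2006).
#' @param horizon Last simulated year (default 2060).
#' @param population_total All-age population at the base year (default 6e7).
#' @param prevalence_years Observed hypertension survey years.
#' @param prevalence_start Prevalence in the youngest age group at the first
#'   observed year.
#' @param prevalence_age_gradient Added prevalence from the youngest to the
#'   oldest age group.
#' @param prevalence_log_slope Annual change of log prevalence (negative =
#'   declining).
#' @param prevalence_noise_sd Log-scale observation noise (0 gives an exact
#'   log-linear series).
#' @param mortality_years Observed mortality years.
#' @param mortality_log_slope Named annual log-rate slopes per cause.
#' @param mortality_noise If `TRUE`, death counts are Poisson draws around
#'   their expectation; if `FALSE`, exact expected counts.
#' @param entrants_per_sex Persons entering at age 35 per sex per year.
#' @param rr Named list of central relative risks per affected transition
#'   type.
#' @param log_rr_se Standard error attached to each log relative risk (used
#'   by the uncertainty module).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 20230901,
                             base_year = 2006, horizon = 2060,
                             population_total = 6e7,
                             prevalence_years = 2003:2017,
                             prevalence_start = 0.28,
                             prevalence_age_gradient = 0.28,
                             prevalence_log_slope = -0.008,
                             prevalence_noise_sd = 0.02,
                             mortality_years = 2007:2016,
                             mortality_log_slope = c(CVD = -0.025, `non-CVD` = -0.012),
                             mortality_noise = TRUE,
                             entrants_per_sex = 380000,
                             rr = list(cvd_incidence = 1.6, ci_incidence = 1.3,
                                       disability_incidence = 1.3,
                                       disability_recovery = 0.85,
                                       cvd_death = 1.9, noncvd_death = 1.15),
                             log_rr_se = 0.05) {
  cfg <- as.list(environment())
  stopifnot(cfg$horizon > cfg$base_year, cfg$population_total > 0,
            cfg$prevalence_start > 0, cfg$prevalence_noise_sd >= 0,
            cfg$entrants_per_sex >= 0)
  if (cfg$prevalence_start + cfg$prevalence_age_gradient >= 1) {
    abort("prevalence_start + prevalence_age_gradient must stay below 1")
  }
  if (any(unlist(cfg$rr) <= 0)) abort("rr values must be positive")
  structure(cfg, class = "synthetic_config")
}

# piecewise-linear all-age density: flat to age 50, declining to 10% at 100
synthetic_age_density <- function() {
  f <- function(a) if_else(a <= 50, 1, 1 - 0.9 * (a - 50) / 50)
  w <- f(0:100)
  w / sum(w)
}

# logistic-in-age transition intensities per affected type; sex-specific
synthetic_hazards <- function(age, sex) {
  male <- sex == "men"
  tibble(
    cvd_incidence = stats::plogis(-8.6 + 0.060 * age) * if_else(male, 1.25, 0.90),
    ci_incidence = stats::plogis(-9.2 + 0.072 * age),
    disability_incidence = stats::plogis(-9.4 + 0.075 * age) * if_else(male, 0.92, 1.08),
    disability_recovery = stats::plogis(0.8 - 0.040 * age),
    death_total = exp(-10.8 + 0.092 * age) * if_else(male, 1.22, 0.88)
  )
}

# base-year condition prevalences by age (marginal, treated as independent)
synthetic_condition_prevalence <- function(age) {
  tibble(
    cvd = stats::plogis(-5.2 + 0.048 * age),
    ci = stats::plogis(-6.6 + 0.058 * age),
    dis = stats::plogis(-6.8 + 0.060 * age)
  )
}

#' Generate a coherent synthetic input bundle
#'
#' Produces every input [run_comparison()] needs: a base-year population
#' spread over the alive states with condition prevalence rising with age;
#' a time-invariant transition-probability table (anchored at the last
#' observed mortality year) that passes [validate_transition_table()];
#' observed hypertension prevalence declining on the log scale; a
#' relative-risk table; cause-specific death counts/exposures with
#' log-linear decline; and annual entrant cohorts. Identical seeds give
#' identical bundles.
#'
#' @param cfg A [synthetic_config()].
#' @return A named list: `population`, `transition_table`, `prevalence`,
#'   `rr`, `mortality`, `entrants`, `state_space`, `config`.
#' @export
generate_all <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  ss <- default_state_space()
  ages <- 35:100

  # --- base population -------------------------------------------------------
  dens <- synthetic_age_density()
  women_frac <- 0.50 + 0.08 * (ages - 35) / 65  # women outlive men
  by_age <- tibble(age = ages, n = cfg$population_total * dens[ages + 1]) %>%
    mutate(women = .data$n * women_frac, men = .data$n - .data$women) %>%
    select("age", "men", "women") %>%
    tidyr::pivot_longer(c("men", "women"), names_to = "sex", values_to = "n")

  occupancy <- by_age %>%
    mutate(synthetic_condition_prevalence(.data$age)) %>%
    tidyr::expand_grid(state = ALIVE_STATES) %>%
    left_join(ss$states, by = "state") %>%
    mutate(count = .data$n *
             if_else(.data$has_cvd, .data$cvd, 1 - .data$cvd) *
             if_else(.data$has_ci, .data$ci, 1 - .data$ci) *
             if_else(.data$has_disability, .data$dis, 1 - .data$dis)) %>%
    select("sex", "age", "state", "count")
  population <- bind_rows(
    occupancy,
    tidyr::expand_grid(sex = SEXES, age = ages, state = DEATH_STATES, count = 0)
  ) %>% arrange(.data$sex, .data$age, .data$state)

  # --- transition table (anchored at the mortality reference year) ----------
  transition_table <- synthetic_transition_table(ss, ages)

  # --- hypertension prevalence ----------------------------------------------
  groups <- age_group_levels()
  p0 <- cfg$prevalence_start +
    cfg$prevalence_age_gradient * (seq_along(groups) - 1) / (length(groups) - 1)
  prevalence <- tidyr::expand_grid(
    age_group = groups, sex = SEXES, year = cfg$prevalence_years
  ) %>%
    left_join(tibble(age_group = groups, p0 = p0), by = "age_group") %>%
    mutate(
      p0 = .data$p0 * if_else(.data$sex == "men", 1.05, 0.95),
      noise = if (cfg$prevalence_noise_sd > 0)
        rnorm(n(), 0, cfg$prevalence_noise_sd) else 0,
      prevalence = .data$p0 *
        exp(cfg$prevalence_log_slope * (.data$year - min(cfg$prevalence_years)) + .data$noise)
    ) %>%
    select("age_group", "sex", "year", "prevalence")
  if (any(prevalence$prevalence <= 0 | prevalence$prevalence >= 1)) {
    abort("generated prevalence left (0, 1); adjust prevalence_start/prevalence_age_gradient")
  }

  # --- relative risks --------------------------------------------------------
  atten <- tibble(age_group = groups,
                  f = 1 - 0.4 * (seq_along(groups) - 1) / (length(groups) - 1))
  rr_tbl <- tidyr::expand_grid(
    transition_type = names(cfg$rr), age_group = groups, sex = SEXES
  ) %>%
    left_join(atten, by = "age_group") %>%
    mutate(rr0 = unname(unlist(cfg$rr)[.data$transition_type]),
           rr = 1 + (.data$rr0 - 1) * .data$f,
           log_rr_se = cfg$log_rr_se) %>%
    select("transition_type", "age_group", "sex", "rr", "log_rr_se")

  # --- observed mortality series --------------------------------------------
  ref <- max(cfg$mortality_years)
  exposure <- by_age %>%
    mutate(age_group = age_group(.data$age)) %>%
    group_by(.data$age_group, .data$sex) %>%
    summarise(exposure = sum(.data$n), .groups = "drop")
  mid_age <- tibble(age_group = groups,
                    mid = pmin(35 + 5 * (seq_along(groups) - 1) + 2, 100))
  mortality <- tidyr::expand_grid(
    age_group = groups, sex = SEXES,
    cause = names(cfg$mortality_log_slope), year = cfg$mortality_years
  ) %>%
    left_join(exposure, by = c("age_group", "sex")) %>%
    left_join(mid_age, by = "age_group") %>%
    mutate(
      base_rate = synthetic_hazards(.data$mid, .data$sex)$death_total *
        if_else(.data$cause == "CVD", 0.30, 0.70),
      rate = .data$base_rate *
        exp(unname(cfg$mortality_log_slope[.data$cause]) * (.data$year - ref)),
      expected = .data$rate * .data$exposure,
      deaths = if (cfg$mortality_noise) rpois_real(.data$expected) else .data$expected
    ) %>%
    select("age_group", "sex", "cause", "year", "deaths", "exposure")

  # --- entrants --------------------------------------------------------------
  entrants <- tidyr::expand_grid(year = cfg$base_year:cfg$horizon, sex = SEXES) %>%
    mutate(count = cfg$entrants_per_sex)

  list(population = population, transition_table = transition_table,
       prevalence = prevalence, rr = rr_tbl, mortality = mortality,
       entrants = entrants, state_space = ss, config = cfg)
}

# rpois for possibly large means, returned as double
rpois_real <- function(mu) as.numeric(stats::rpois(length(mu), mu))

# build the time-invariant transition table on the default state space
synthetic_transition_table <- function(ss, ages) {
  map <- affected_transition_map(ss)
  st <- ss$states

  grid <- tidyr::expand_grid(sex = SEXES, age = ages) %>%
    mutate(synthetic_hazards(.data$age, .data$sex))

  rows <- tidyr::expand_grid(grid, map) %>%
    left_join(st %>% select(from_state = "state", f_cvd = "has_cvd",
                            f_dis = "has_disability", f_dem = "is_dementia"),
              by = "from_state") %>%
    mutate(probability = dplyr::case_when(
      transition_type == "cvd_incidence" ~ cvd_incidence,
      transition_type == "ci_incidence" ~ ci_incidence,
      transition_type == "disability_incidence" ~ disability_incidence *
        if_else(f_dem | (from_state %in% c("CI", "CVD_CI")), 1.6, 1),
      transition_type == "disability_recovery" ~ disability_recovery,
      transition_type == "cvd_death" ~ death_total * 0.30 *
        if_else(f_cvd, 2.0, 1) * if_else(f_dem, 1.3, 1),
      transition_type == "noncvd_death" ~ death_total * 0.70 *
        if_else(f_dem, 1.6, if_else(f_dis, 1.25, 1))
    )) %>%
    select("sex", "age", "from_state", "to_state", "probability")

  tt <- complete_stay_probability(rows, ss)
  if (any(tt$probability < 0)) {
    abort("synthetic transition rows exceed probability 1; lower the hazard parameters")
  }
  tt
}
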