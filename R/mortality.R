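#' Cause-specific mortality trend projection
#'
#' Observed death counts and person-year exposures per (5-year age group,
#' sex, cause in {CVD, non-CVD}, calendar year) are fitted with a per-stratum
#' Poisson regression of deaths on calendar year with a log-exposure offset
#' (a log-linear trend in the rate). Projected rates are turned into
#' year-specific multipliers on the corresponding death-transition
#' probabilities, relative to a base year, with the stay probability
#' absorbing the complement so rows stay stochastic.
#'
#' @name mortality_projection
NULL

#' Fit per-stratum Poisson log-linear mortality trends
#'
#' @param series Data frame `age_group`, `sex`, `cause`, `year`, `deaths`,
#'   `exposure` (person-years, positive).
#' @param window Length-2 year range of observations to use, e.g.
#'   `c(2007, 2016)` or the shorter `c(2010, 2016)` window; default uses all
#'   years present.
#' @return A `mortality_trend_fit` tibble: `age_group`, `sex`, `cause`,
#'   `intercept` (log rate at the reference year, the window end),
#'   `intercept_se`, `slope` (log-rate change per year), `slope_se`; with
#'   attributes `reference_year` and `window`. Strata whose deaths are all
#'   zero get slope 0 (and intercept `-Inf` replaced by the log of a tenth
#'   of a death over the window exposure) with a warning rather than an
#'   error.
#' @export
fit_loglinear_trend <- function(series, window = NULL) {
  series <- as_tibble(series)
  check_columns(series, c("age_group", "sex", "cause", "year", "deaths", "exposure"),
                "mortality series")
  if (any(series$exposure <= 0)) abort("exposure must be positive")
  if (any(series$deaths < 0)) abort("deaths must be non-negative")
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    series <- filter(series, .data$year >= window[1], .data$year <= window[2])
  } else {
    window <- range(series$year)
  }
  ref <- max(series$year)

  fits <- series %>%
    group_by(.data$age_group, .data$sex, .data$cause) %>%
    group_split() %>%
    purrr::map(function(d) {
      if (dplyr::n_distinct(d$year) < 2) {
        abort(sprintf("stratum %s/%s/%s has fewer than 2 observed years",
                      d$age_group[1], d$sex[1], d$cause[1]))
      }
      base <- tibble(age_group = d$age_group[1], sex = d$sex[1], cause = d$cause[1])
      if (all(d$deaths == 0)) {
        bamsim_warn(sprintf("stratum %s/%s/%s has no deaths; trend slope set to 0",
                            base$age_group, base$sex, base$cause),
                    class = "bamsim_zero_deaths")
        return(mutate(base,
                      intercept = log(0.1 / sum(d$exposure)), intercept_se = NA_real_,
                      slope = 0, slope_se = NA_real_))
      }
      # expected (non-integer) counts are legitimate inputs; the Poisson
      # likelihood still gives the right point estimates, so muffle that warning
      m <- withCallingHandlers(
        glm(deaths ~ I(year - ref) + offset(log(exposure)),
            family = poisson(), data = d),
        warning = function(w) {
          if (grepl("non-integer", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      se <- sqrt(diag(vcov(m)))
      mutate(base,
             intercept = unname(coef(m)[1]), intercept_se = unname(se[1]),
             slope = unname(coef(m)[2]), slope_se = unname(se[2]))
    }) %>%
    bind_rows() %>%
    arrange(.data$age_group, .data$sex, .data$cause)

  structure(fits, reference_year = ref, window = window,
            class = c("mortality_trend_fit", class(fits)))
}

#' The seven mortality-trend sensitivity scenarios
#'
#' Equally spaced multipliers on the fitted slope from 0 (no further
#' improvement in mortality) to 2 (a doubling of the declining trend), with
#' the central projection at 1.
#'
#' @return A tibble `label`, `slope_multiplier`.
#' @export
mortality_scenarios <- function() {
  tibble(
    label = c("no_improvement", "one_third", "two_thirds", "central",
              "four_thirds", "five_thirds", "doubled"),
    slope_multiplier = seq(0, 2, length.out = 7)
  )
}

#' Project mortality rates under a trend scenario
#'
#' `rate(y) = exp(intercept + slope_multiplier * slope * (y - reference))`
#' per stratum: multiplier 1 is the central projection, 0 freezes rates at
#' the reference-year fitted level.
#'
#' @param fit A [fit_loglinear_trend()] result.
#' @param horizon Last year to project to.
#' @param slope_multiplier Non-negative scenario multiplier on the slope.
#' @param from First projected year (default the fit's window start, so the
#'   fitted window is covered too).
#' @return A tibble `age_group`, `sex`, `cause`, `year`, `rate` (deaths per
#'   person-year).
#' @export
project_rates <- function(fit, horizon, slope_multiplier = 1, from = NULL) {
  if (slope_multiplier < 0) abort("slope_multiplier must be non-negative")
  ref <- attr(fit, "reference_year")
  if (horizon < ref) abort("horizon must not precede the last observed year")
  from <- from %||% attr(fit, "window")[1]
  tidyr::expand_grid(
    as_tibble(fit) %>% select("age_group", "sex", "cause", "intercept", "slope"),
    year = seq(from, horizon)
  ) %>%
    mutate(rate = exp(.data$intercept + slope_multiplier * .data$slope * (.data$year - ref))) %>%
    select("age_group", "sex", "cause", "year", "rate")
}

#' Death-transition multipliers relative to a base year
#'
#' `multiplier(y) = rate(y) / rate(base_year)` per (age group, sex, cause).
#'
#' @param projected Output of [project_rates()], covering `base_year`.
#' @param base_year Year whose rates anchor the transition probabilities
#'   (multiplier exactly 1 there).
#' @return A tibble `year`, `age_group`, `sex`, `cause`, `multiplier`.
#' @export
death_tp_multipliers <- function(projected, base_year) {
  projected <- as_tibble(projected)
  check_columns(projected, c("age_group", "sex", "cause", "year", "rate"),
                "projected rates")
  base <- projected %>%
    filter(.data$year == base_year) %>%
    select("age_group", "sex", "cause", base_rate = "rate")
  if (nrow(base) == 0) abort(sprintf("projected rates do not cover base year %d", base_year))
  if (any(base$base_rate <= 0)) abort("base-year rate is zero: multipliers undefined")
  projected %>%
    left_join(base, by = c("age_group", "sex", "cause")) %>%
    mutate(multiplier = .data$rate / .data$base_rate) %>%
    select("year", "age_group", "sex", "cause", "multiplier")
}

#' Scale death-transition probabilities by projected multipliers
#'
#' Expands a time-invariant transition table over the multiplier years and
#' multiplies each death-transition probability by its stratum-year
#' multiplier (5-year age-group multipliers apply to every single age in the
#' group). The stay probability absorbs the change; adjusted probabilities
#' are clipped into `[0, 1]` with a warning, and a stay probability driven
#' below zero clips to zero with the row renormalised (also warned).
#'
#' @param tt Transition table with explicit stay rows (time-invariant or
#'   year-specific).
#' @param multipliers Output of [death_tp_multipliers()].
#' @param ss A [state_space].
#' @return A year-specific transition table covering the multiplier years.
#' @export
apply_death_multipliers <- function(tt, multipliers, ss = default_state_space()) {
  tt <- as_tibble(tt)
  multipliers <- as_tibble(multipliers)
  check_columns(multipliers, c("year", "age_group", "sex", "cause", "multiplier"),
                "multipliers")
  if (!"year" %in% names(tt)) {
    tt <- tidyr::expand_grid(year = sort(unique(multipliers$year)), tt)
  }
  cause_of <- ss$states %>%
    filter(.data$is_death) %>%
    select(to_state = "state", cause = "death_cause")

  work <- tt %>%
    mutate(.age_group = age_group(.data$age)) %>%
    left_join(cause_of, by = "to_state") %>%
    left_join(multipliers,
              by = c(year = "year", .age_group = "age_group", sex = "sex",
                     cause = "cause")) %>%
    mutate(multiplier = dplyr::coalesce(.data$multiplier, 1),
           shift = .data$probability * (.data$multiplier - 1))

  absorb <- work %>%
    filter(.data$shift != 0) %>%
    group_by(.data$year, .data$sex, .data$age, .data$from_state) %>%
    summarise(stay_shift = -sum(.data$shift), .groups = "drop")

  out <- work %>%
    mutate(probability = .data$probability + .data$shift) %>%
    left_join(absorb, by = c("year", "sex", "age", "from_state")) %>%
    mutate(probability = if_else(
      .data$from_state == .data$to_state & !is.na(.data$stay_shift),
      .data$probability + .data$stay_shift, .data$probability)) %>%
    select(-"shift", -"stay_shift", -"cause", -".age_group")

  n_clip <- sum(out$probability < 0 | out$probability > 1)
  if (n_clip > 0) {
    bamsim_warn(sprintf(
      "mortality scaling clipped %d transition probabilities into [0, 1]; affected rows renormalised",
      n_clip), class = "bamsim_clip")
    out <- out %>%
      mutate(probability = pmin(pmax(.data$probability, 0), 1)) %>%
      group_by(.data$year, .data$sex, .data$age, .data$from_state) %>%
      mutate(probability = .data$probability / sum(.data$probability)) %>%
      ungroup()
  }
  out %>%
    select(-"multiplier") %>%
    select(any_of(c("year", "sex", "age", "from_state", "to_state", "probability")))
}

#' @export
tidy.mortality_trend_fit <- function(x, ...) {
  as_tibble(x) %>% mutate(reference_year = attr(x, "reference_year"))
}

#' @export
glance.mortality_trend_fit <- function(x, ...) {
  w <- attr(x, "window")
  tibble(
    n_strata = nrow(x),
    reference_year = attr(x, "reference_year"),
    window_start = w[1], window_end = w[2],
    mean_slope = mean(x$slope)
  )
}
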