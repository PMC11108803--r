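#' Hypertension prevalence trends and future scenarios
#'
#' Observed prevalence (fraction of each 5-year age group by sex with
#' uncontrolled/untreated hypertension, by survey year) is extrapolated on
#' the log scale, and three futures are constructed from it: the fitted
#' trend continuing (`baseline`), the last observed year held flat
#' (`constant`), and a log-linear path halving the last observed value by a
#' target year (`optimistic`).
#'
#' @name prevalence_scenarios
NULL

#' Fit per-stratum log-linear prevalence trends
#'
#' Ordinary least squares of `log(prevalence)` on calendar year within each
#' (age group, sex) stratum.
#'
#' @param observed Data frame `age_group`, `sex`, `year`, `prevalence` with
#'   prevalences in `(0, 1]`; at least two observed years per stratum.
#' @return A `prevalence_trend_fit`: tibble of `age_group`, `sex`,
#'   `intercept` (fitted log prevalence at the last observed year), `slope`
#'   (log change per year), `slope_se`, `n_years`; the last observed year is
#'   carried as attribute `reference_year`.
#' @export
fit_prevalence_trend <- function(observed) {
  observed <- as_tibble(observed)
  check_columns(observed, c("age_group", "sex", "year", "prevalence"),
                "observed prevalence")
  check_sex(observed$sex, "observed prevalence")
  if (any(observed$prevalence <= 0)) {
    abort(paste0(
      "observed prevalence contains zero or negative values; ",
      "floor them at a small positive value (e.g. 1e-4) before fitting"))
  }
  if (any(observed$prevalence > 1)) abort("prevalence must lie in (0, 1]")
  ref <- max(observed$year)
  fits <- observed %>%
    group_by(.data$age_group, .data$sex) %>%
    group_split() %>%
    purrr::map(function(d) {
      if (dplyr::n_distinct(d$year) < 2) {
        abort(sprintf("stratum %s/%s has fewer than 2 observed years",
                      d$age_group[1], d$sex[1]))
      }
      m <- lm(log(prevalence) ~ I(year - ref), data = d)
      # a noiseless series fits exactly; summary.lm warns about that, harmlessly
      se2 <- withCallingHandlers(
        sqrt(diag(vcov(m)))[2],
        warning = function(w) {
          if (grepl("essentially perfect fit", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      tibble(
        age_group = d$age_group[1], sex = d$sex[1],
        intercept = unname(coef(m)[1]), slope = unname(coef(m)[2]),
        slope_se = se2, n_years = dplyr::n_distinct(d$year)
      )
    }) %>%
    bind_rows() %>%
    arrange(.data$age_group, .data$sex)
  structure(fits, reference_year = ref,
            class = c("prevalence_trend_fit", class(fits)))
}

#' Construct a prevalence scenario series
#'
#' For years up to the last observed year every scenario returns the
#' observed values, so all scenarios coincide over the observation window.
#' From the following year on: `baseline` follows the fitted log-linear
#' trend (capped into `[floor, 1]`); `constant` repeats the last observed
#' value; `optimistic` moves log-linearly from the last observed value to
#' `reduction_fraction` times it at `target_year` (multiplier
#' `exp(log(reduction_fraction) * (y - y_last) / (target_year - y_last))`),
#' or linearly when `interpolation = "linear"`.
#'
#' @param fit A [fit_prevalence_trend()] result.
#' @param observed The observed series the fit was computed from.
#' @param scenario One of `"baseline"`, `"constant"`, `"optimistic"`.
#' @param horizon Last calendar year of the series (default 2060).
#' @param target_year Year by which the optimistic reduction is complete
#'   (default 2060).
#' @param reduction_fraction Optimistic multiplier reached at `target_year`
#'   (default 0.5, i.e. a 50% reduction).
#' @param floor Lower cap for the extrapolated baseline (default `1e-4`).
#' @param interpolation `"loglinear"` (default) or `"linear"` path for the
#'   optimistic scenario.
#' @return A tibble `scenario`, `age_group`, `sex`, `year`, `prevalence`
#'   covering every observed year through `horizon`.
#' @export
scenario_prevalence <- function(fit, observed, scenario = c("baseline", "constant", "optimistic"),
                                horizon = 2060, target_year = 2060,
                                reduction_fraction = 0.5, floor = 1e-4,
                                interpolation = c("loglinear", "linear")) {
  scenario <- match.arg(scenario)
  interpolation <- match.arg(interpolation)
  stopifnot(reduction_fraction > 0, reduction_fraction <= 1)
  observed <- as_tibble(observed)
  ref <- attr(fit, "reference_year")
  if (target_year <= ref) abort("target_year must be after the last observed year")
  first_year <- min(observed$year)
  if (horizon < first_year) abort(sprintf("horizon predates first observed year %d", first_year))

  last_obs <- observed %>%
    filter(.data$year == ref) %>%
    select("age_group", "sex", p_ref = "prevalence")

  future_years <- seq(ref + 1, horizon)
  if (horizon <= ref) {
    future <- tibble(age_group = character(), sex = character(),
                     year = integer(), prevalence = numeric())
  } else {
    grid <- tidyr::expand_grid(
      as_tibble(fit) %>% select("age_group", "sex", "intercept", "slope"),
      year = future_years
    ) %>% left_join(last_obs, by = c("age_group", "sex"))
    future <- switch(scenario,
      baseline = grid %>%
        mutate(prevalence = exp(.data$intercept + .data$slope * (.data$year - ref))),
      constant = grid %>% mutate(prevalence = .data$p_ref),
      optimistic = {
        frac <- (grid$year - ref) / (target_year - ref)
        frac <- pmin(frac, 1)  # hold at the target level past target_year
        mult <- if (interpolation == "loglinear") {
          exp(log(reduction_fraction) * frac)
        } else {
          1 + (reduction_fraction - 1) * frac
        }
        mutate(grid, prevalence = .data$p_ref * mult)
      }
    )
    n_cap <- sum(future$prevalence < floor | future$prevalence > 1)
    if (n_cap > 0) {
      bamsim_warn(sprintf("capped %d extrapolated prevalence values into [%g, 1]",
                          n_cap, floor), class = "bamsim_cap")
    }
    future <- future %>%
      mutate(prevalence = pmin(pmax(.data$prevalence, floor), 1)) %>%
      select("age_group", "sex", "year", "prevalence")
  }

  bind_rows(
    observed %>% select("age_group", "sex", "year", "prevalence"),
    future
  ) %>%
    filter(.data$year <= horizon) %>%
    mutate(scenario = scenario, .before = 1) %>%
    arrange(.data$age_group, .data$sex, .data$year)
}

#' @export
tidy.prevalence_trend_fit <- function(x, ...) {
  as_tibble(x) %>%
    mutate(reference_year = attr(x, "reference_year"))
}

#' @export
glance.prevalence_trend_fit <- function(x, ...) {
  tibble(
    n_strata = nrow(x),
    reference_year = attr(x, "reference_year"),
    mean_slope = mean(x$slope),
    min_slope = min(x$slope),
    max_slope = max(x$slope)
  )
}
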