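#' Population attributable risk fraction (Levin's formula)
#'
#' `parf(p, rr)` is the proportion of disease burden that would be removed if
#' the prevalence `p` of an exposure with relative risk `rr` fell to zero:
#' `p (rr - 1) / (1 + p (rr - 1))`.
#'
#' @param p Exposure prevalence, in `[0, 1]`. Vectorised.
#' @param rr Relative risk comparing exposed with unexposed, `> 0`.
#'   Vectorised.
#' @return Numeric vector of attributable fractions.
#' @export
#' @examples
#' parf(0.3, 2)  # 0.3/1.3
parf <- function(p, rr) {
  check_parf_args(p, rr)
  e <- p * (rr - 1)
  denom <- 1 + e
  if (any(denom <= 0)) abort("1 + p(rr - 1) <= 0: attributable fraction undefined")
  e / denom
}

#' Potential impact fraction for a prevalence shift
#'
#' `delta_parf(p, p_prime, rr)` is the proportional change in burden when
#' prevalence moves from `p` to `p_prime` rather than to zero:
#' `(p - p_prime)(rr - 1) / (1 + p (rr - 1))` -- the potential impact
#' fraction (PIF) for a discrete risk factor. It is positive when prevalence
#' falls and `rr > 1` (burden reduced), negative when prevalence falls and
#' `rr < 1` (the transition, e.g. recovery, becomes more likely), and reduces
#' to [parf()] when `p_prime = 0`.
#'
#' @param p Prevalence before the shift, in `[0, 1]`.
#' @param p_prime Prevalence after the shift, in `[0, 1]`.
#' @inheritParams parf
#' @return Numeric vector of impact fractions.
#' @export
#' @examples
#' delta_parf(0.4, 0.2, 1.5)  # 0.1/1.2
delta_parf <- function(p, p_prime, rr) {
  check_parf_args(p, rr)
  if (any(p_prime < 0 | p_prime > 1)) abort("p_prime must lie in [0, 1]")
  denom <- 1 + p * (rr - 1)
  if (any(denom <= 0)) abort("1 + p(rr - 1) <= 0: impact fraction undefined")
  (p - p_prime) * (rr - 1) / denom
}

check_parf_args <- function(p, rr) {
  if (any(!is.finite(p) | p < 0 | p > 1)) abort("p must lie in [0, 1]")
  if (any(!is.finite(rr) | rr <= 0)) abort("rr must be positive and finite")
  invisible(NULL)
}

#' Impact fractions per stratum and affected transition type
#'
#' Joins baseline and counterfactual prevalence series with the
#' relative-risk table and evaluates [delta_parf()] per (year, age group,
#' sex, transition type). Baseline prevalence plays the role of `p`,
#' counterfactual of `p_prime`, so the baseline scenario keeps its original
#' transition probabilities and counterfactual scenarios are adjusted
#' relative to it.
#'
#' @param baseline_prev,scenario_prev Prevalence series (columns `age_group`,
#'   `sex`, `year`, `prevalence`) sharing strata and years.
#' @param rr_table Relative risks (columns `transition_type`, `age_group`,
#'   `sex`, `rr`).
#' @return A tibble `year`, `age_group`, `sex`, `transition_type`, `delta`.
#' @export
delta_parf_table <- function(baseline_prev, scenario_prev, rr_table) {
  baseline_prev <- as_tibble(baseline_prev)
  scenario_prev <- as_tibble(scenario_prev)
  check_columns(baseline_prev, c("age_group", "sex", "year", "prevalence"),
                "baseline prevalence")
  check_columns(scenario_prev, c("age_group", "sex", "year", "prevalence"),
                "scenario prevalence")
  check_columns(rr_table, c("transition_type", "age_group", "sex", "rr"), "RR table")
  joined <- baseline_prev %>%
    select("age_group", "sex", "year", p = "prevalence") %>%
    inner_join(scenario_prev %>%
                 select("age_group", "sex", "year", p_prime = "prevalence"),
               by = c("age_group", "sex", "year"))
  if (nrow(joined) != nrow(baseline_prev)) {
    abort("baseline and scenario prevalence series do not share strata and years")
  }
  joined %>%
    inner_join(as_tibble(rr_table) %>%
                 select("transition_type", "age_group", "sex", "rr"),
               by = c("age_group", "sex"),
               relationship = "many-to-many") %>%
    mutate(delta = delta_parf(.data$p, .data$p_prime, .data$rr)) %>%
    select("year", "age_group", "sex", "transition_type", "delta") %>%
    arrange(.data$year, .data$age_group, .data$sex, .data$transition_type)
}

#' Adjust transition probabilities by impact fractions
#'
#' Applies `tp' = tp * (1 - delta)` to every transition cell mapped to an
#' affected transition type, with the stay probability absorbing the change
#' so each row still sums to one. A single rule serves all six affected
#' types: for recovery transitions the stratum relative risk is below one,
#' so a prevalence decline yields a negative `delta` and the recovery
#' probability rises. Unmapped transitions are untouched, and zero deltas
#' return the input unchanged.
#'
#' @param tt A transition table with explicit stay rows; must carry a `year`
#'   column when `deltas` vary by year (a time-invariant table is expanded
#'   over the delta years).
#' @param deltas Output of [delta_parf_table()].
#' @param mapping Transition-type map, as from [affected_transition_map()].
#' @param ss A [state_space].
#' @return The adjusted, year-specific transition table.
#' @export
apply_delta_parf <- function(tt, deltas, mapping = affected_transition_map(ss),
                             ss = default_state_space()) {
  tt <- as_tibble(tt)
  deltas <- as_tibble(deltas)
  check_columns(deltas, c("year", "age_group", "sex", "transition_type", "delta"),
                "deltas")
  if (any(abs(deltas$delta) >= 1)) {
    abort("|delta| >= 1: impact fraction would not leave a valid probability")
  }
  if (!"year" %in% names(tt)) {
    tt <- tidyr::expand_grid(year = sort(unique(deltas$year)), tt)
  }
  adj <- deltas %>%
    inner_join(as_tibble(mapping), by = "transition_type",
               relationship = "many-to-many")

  work <- tt %>%
    mutate(.row = dplyr::row_number(), .age_group = age_group(.data$age)) %>%
    left_join(adj,
              by = c(year = "year", .age_group = "age_group", sex = "sex",
                     from_state = "from_state", to_state = "to_state")) %>%
    mutate(delta = dplyr::coalesce(.data$delta, 0),
           shift = -.data$probability * .data$delta)

  # stay row absorbs the summed shift of its row's adjusted cells
  absorb <- work %>%
    filter(.data$shift != 0) %>%
    group_by(.data$year, .data$sex, .data$age, .data$from_state) %>%
    summarise(stay_shift = -sum(.data$shift), .groups = "drop")

  out <- work %>%
    mutate(probability = .data$probability + .data$shift) %>%
    left_join(absorb, by = c("year", "sex", "age", "from_state")) %>%
    mutate(probability = if_else(
      .data$from_state == .data$to_state & !is.na(.data$stay_shift),
      .data$probability + .data$stay_shift, .data$probability))

  bad_stay <- out %>%
    filter(.data$from_state == .data$to_state, .data$probability < 0)
  if (nrow(bad_stay) > 0) {
    r <- bad_stay[1, ]
    abort(sprintf(
      "impact-fraction adjustment drives the stay probability negative for year %s, sex %s, age %s, state %s",
      r$year, r$sex, r$age, r$from_state))
  }
  n_clip <- sum(out$probability < 0 | out$probability > 1)
  if (n_clip > 0) {
    bamsim_warn(sprintf("clipped %d adjusted transition probabilities into [0, 1]", n_clip),
                class = "bamsim_clip")
    out$probability <- pmin(pmax(out$probability, 0), 1)
  }
  out %>%
    select(-"shift", -"delta", -"stay_shift", -".age_group", -".row") %>%
    select(any_of(c("year", "sex", "age", "from_state", "to_state", "probability")))
}
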