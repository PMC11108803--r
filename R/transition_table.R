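#' Transition-probability tables
#'
#' One-year transition probabilities are held in tidy form: one row per
#' (optionally `year`,) `sex`, `age`, `from_state`, `to_state` with a
#' `probability` in `[0, 1]`. A table without a `year` column is
#' time-invariant. The stay probability (`from_state == to_state`) may be
#' left implicit; [complete_stay_probability()] makes it explicit, and the
#' validator and projection engine expect explicit rows that sum to one.
#'
#' @name transition_table
NULL

#' Make stay probabilities explicit
#'
#' Adds, for every (year, sex, age, from-state) group of an alive from-state,
#' a `from -> from` row carrying one minus the sum of the listed outflows.
#' Existing stay rows are kept as given.
#'
#' @param tt A transition table (see [transition_table]).
#' @param ss A [state_space].
#' @return The table with explicit stay rows.
#' @export
complete_stay_probability <- function(tt, ss) {
  tt <- as_tibble(tt)
  check_columns(tt, c("sex", "age", "from_state", "to_state", "probability"),
                "transition table")
  keys <- intersect(c("year", "sex", "age", "from_state"), names(tt))
  have_stay <- tt %>%
    filter(.data$from_state == .data$to_state) %>%
    distinct(across(all_of(keys)))
  stays <- tt %>%
    group_by(across(all_of(keys))) %>%
    summarise(probability = 1 - sum(.data$probability[.data$from_state != .data$to_state]),
              .groups = "drop") %>%
    anti_join(have_stay, by = keys) %>%
    mutate(to_state = .data$from_state)
  bind_rows(tt, stays) %>%
    arrange(across(any_of(c("year", "sex", "age", "from_state", "to_state"))))
}

#' Validate a transition table against a state space
#'
#' Diagnostic check of the structural invariants: probabilities within
#' `[0, 1]`, no positive probability on a transition the state space
#' disallows, and every (year, sex, age, from-state) row summing to one
#' within `tol`. Never raises; returns the violations found.
#'
#' @param tt A transition table with explicit stay probabilities.
#' @param ss A [state_space].
#' @param tol Tolerance on row sums (default `1e-9`).
#' @return A tibble with columns `year` (NA for time-invariant tables),
#'   `sex`, `age`, `from_state`, `rule`, `detail`; zero rows when the table
#'   is valid.
#' @export
validate_transition_table <- function(tt, ss, tol = 1e-9) {
  tt <- as_tibble(tt)
  check_columns(tt, c("sex", "age", "from_state", "to_state", "probability"),
                "transition table")
  if (!"year" %in% names(tt)) tt$year <- NA_integer_
  empty <- tibble(year = integer(), sex = character(), age = integer(),
                  from_state = character(), rule = character(), detail = character())

  out_of_range <- tt %>%
    filter(.data$probability < 0 | .data$probability > 1 | !is.finite(.data$probability)) %>%
    mutate(rule = "probability_range",
           detail = sprintf("%s->%s probability %g outside [0,1]",
                            .data$from_state, .data$to_state, .data$probability))

  disallowed <- tt %>%
    filter(.data$probability > 0) %>%
    anti_join(ss$transitions, by = c("from_state", "to_state")) %>%
    mutate(rule = "disallowed_transition",
           detail = sprintf("positive probability %g on disallowed %s->%s",
                            .data$probability, .data$from_state, .data$to_state))

  bad_sum <- tt %>%
    group_by(.data$year, .data$sex, .data$age, .data$from_state) %>%
    summarise(row_sum = sum(.data$probability), .groups = "drop") %>%
    filter(abs(.data$row_sum - 1) > tol) %>%
    mutate(rule = "row_sum",
           detail = sprintf("row sums to %.12g, not 1", .data$row_sum))

  bind_rows(empty,
            select(out_of_range, all_of(names(empty))),
            select(disallowed, all_of(names(empty))),
            select(bad_sum, all_of(names(empty)))) %>%
    arrange(.data$year, .data$sex, .data$age, .data$from_state, .data$rule)
}

# --- internal dense representation -----------------------------------------

# Convert a tidy transition table into a dense array P[sex, age, from, to]
# for one year (tt must be time-invariant or pre-filtered to a single year).
tt_to_array <- function(tt, ss, ages, sexes = SEXES) {
  states <- states_of(ss)
  S <- length(states)
  P <- array(0, dim = c(length(sexes), length(ages), S, S),
             dimnames = list(sexes, ages, states, states))
  # death states are absorbing
  for (d in which(ss$states$is_death)) P[, , d, d] <- 1
  i_sex <- match(tt$sex, sexes)
  i_age <- match(tt$age, ages)
  i_from <- match(tt$from_state, states)
  i_to <- match(tt$to_state, states)
  if (anyNA(i_sex)) abort("transition table has a sex not in the model")
  if (anyNA(i_age)) abort("transition table has an age outside the modelled ages")
  if (anyNA(i_from) || anyNA(i_to)) abort("transition table references unknown states")
  P[cbind(i_sex, i_age, i_from, i_to)] <- tt$probability
  P
}

# Split a transition table into a per-year list of dense arrays covering
# `years`; a table without a year column (or with NA years) is recycled.
tt_year_arrays <- function(tt, ss, ages, years, sexes = SEXES) {
  if (!"year" %in% names(tt) || all(is.na(tt$year))) {
    P <- tt_to_array(tt, ss, ages, sexes)
    return(lapply(years, function(y) P))
  }
  missing_years <- setdiff(years, unique(tt$year))
  if (length(missing_years) > 0) {
    abort(sprintf("transition table is missing year%s: %s",
                  if (length(missing_years) > 1) "s" else "",
                  paste(missing_years, collapse = ", ")))
  }
  by_year <- split(tt, tt$year)
  lapply(years, function(y) tt_to_array(by_year[[as.character(y)]], ss, ages, sexes))
}
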