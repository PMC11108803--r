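#' Health-state spaces
#'
#' A `state_space` describes the compartments of the cohort model: a set of
#' alive states defined by three condition flags (cardiovascular disease,
#' cognitive impairment, disability), one or more absorbing death states with
#' a cause label, and the set of allowed one-year transitions. Dementia is not
#' an independent flag: a state is a dementia state exactly when cognitive
#' impairment and disability coexist.
#'
#' @param states A data frame with columns `state` (unique identifier),
#'   `has_cvd`, `has_ci`, `has_disability` (logical; ignored for death
#'   states), `is_death` (logical) and `death_cause` ("CVD", "non-CVD" or
#'   "none").
#' @param transitions A data frame with columns `from_state`, `to_state`
#'   listing allowed transitions between distinct states. Staying in an alive
#'   state is always allowed and need not be listed.
#'
#' @return An object of class `state_space`: a list with tibbles `states`
#'   (including the derived `is_dementia` flag) and `transitions` (including
#'   stay transitions), plus the entrant state.
#' @export
state_space <- function(states, transitions) {
  states <- as_tibble(states)
  check_columns(states, c("state", "has_cvd", "has_ci", "has_disability",
                          "is_death", "death_cause"), "states")
  if (anyDuplicated(states$state)) abort("state identifiers must be unique")
  states <- states %>%
    mutate(
      has_cvd = .data$has_cvd & !.data$is_death,
      has_ci = .data$has_ci & !.data$is_death,
      has_disability = .data$has_disability & !.data$is_death,
      is_dementia = .data$has_ci & .data$has_disability
    )
  alive <- states$state[!states$is_death]
  dead <- states$state[states$is_death]
  if (length(dead) < 1) abort("at least one death state is required")
  if (any(states$death_cause[!states$is_death] != "none")) {
    abort("alive states must have death_cause 'none'")
  }

  transitions <- as_tibble(transitions)
  check_columns(transitions, c("from_state", "to_state"), "transitions")
  unknown <- setdiff(c(transitions$from_state, transitions$to_state), states$state)
  if (length(unknown) > 0) {
    abort(sprintf("transitions reference unknown states: %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  if (any(transitions$from_state %in% dead)) {
    abort("death states are absorbing: no transition out of a death state is allowed")
  }
  # every alive state must be able to die of every modelled cause
  need <- tidyr::expand_grid(from_state = alive, to_state = dead)
  lacking <- anti_join(need, transitions, by = c("from_state", "to_state"))
  if (nrow(lacking) > 0) {
    abort(sprintf("every alive state needs a transition to every death state; missing: %s",
                  paste(paste0(lacking$from_state, "->", lacking$to_state), collapse = ", ")))
  }
  # stay transitions for alive states are implicit; make them explicit
  transitions <- bind_rows(transitions,
                           tibble(from_state = alive, to_state = alive)) %>%
    distinct(.data$from_state, .data$to_state)

  entrant <- states %>%
    filter(!.data$is_death, !.data$has_cvd, !.data$has_ci, !.data$has_disability) %>%
    pull("state")
  if (length(entrant) != 1) {
    abort("exactly one disease-free alive state (all flags FALSE) is required as the entrant state")
  }

  structure(
    list(states = states, transitions = transitions, entrant_state = entrant),
    class = "state_space"
  )
}

#' Default ten-state space
#'
#' Eight alive states -- disease-free (FREE), CVD, cognitive impairment (CI),
#' CVD+CI, disability (DIS), CVD+DIS, dementia (DEM, the coexistence of
#' cognitive impairment and disability) and CVD+DEM -- plus two absorbing
#' death states (CVD_DEATH, NONCVD_DEATH). Allowed moves: acquisition of CVD
#' and of cognitive impairment are irreversible; disability can be acquired
#' at any point and recovered from only while cognitively intact; at most one
#' condition is acquired per year, so dementia is entered from CI (acquiring
#' disability) or from DIS (acquiring cognitive impairment), never directly
#' from FREE; every alive state can move to either death state.
#'
#' @param allow_cvd_from_dementia If `TRUE`, also allow DEM -> CVD_DEM
#'   (acquisition of CVD after dementia onset). Off by default, so the only
#'   exits from the dementia states are the death states.
#' @return A [state_space].
#' @export
#' @examples
#' ss <- default_state_space()
#' nrow(ss$states)
default_state_space <- function(allow_cvd_from_dementia = FALSE) {
  flags <- tibble(
    state = ALL_STATES,
    has_cvd = ALL_STATES %in% c("CVD", "CVD_CI", "CVD_DIS", "CVD_DEM"),
    has_ci = ALL_STATES %in% c("CI", "CVD_CI", "DEM", "CVD_DEM"),
    has_disability = ALL_STATES %in% c("DIS", "CVD_DIS", "DEM", "CVD_DEM"),
    is_death = ALL_STATES %in% DEATH_STATES,
    death_cause = dplyr::case_when(
      ALL_STATES == "CVD_DEATH" ~ "CVD",
      ALL_STATES == "NONCVD_DEATH" ~ "non-CVD",
      TRUE ~ "none"
    )
  )
  moves <- tibble::tribble(
    ~from_state, ~to_state,
    "FREE",    "CVD",      # CVD incidence
    "FREE",    "CI",       # cognitive-impairment incidence
    "FREE",    "DIS",      # disability incidence
    "CVD",     "CVD_CI",
    "CVD",     "CVD_DIS",
    "CI",      "CVD_CI",
    "CI",      "DEM",      # disability incidence completing dementia
    "CVD_CI",  "CVD_DEM",
    "DIS",     "CVD_DIS",
    "DIS",     "DEM",      # cognitive-impairment incidence completing dementia
    "DIS",     "FREE",     # disability recovery (cognitively intact only)
    "CVD_DIS", "CVD_DEM",
    "CVD_DIS", "CVD"       # disability recovery
  )
  if (allow_cvd_from_dementia) {
    moves <- bind_rows(moves, tibble(from_state = "DEM", to_state = "CVD_DEM"))
  }
  deaths <- tidyr::expand_grid(from_state = ALIVE_STATES, to_state = DEATH_STATES)
  state_space(flags, bind_rows(moves, deaths))
}

#' @export
print.state_space <- function(x, ...) {
  alive <- sum(!x$states$is_death)
  cat(sprintf("<state_space> %d states (%d alive, %d death), %d allowed transitions\n",
              nrow(x$states), alive, nrow(x$states) - alive, nrow(x$transitions)))
  cat("entrant state:", x$entrant_state, "\n")
  invisible(x)
}

#' States of a state space
#' @param ss A [state_space].
#' @param alive_only Return only alive states?
#' @return Character vector of state identifiers in canonical order.
#' @export
states_of <- function(ss, alive_only = FALSE) {
  s <- ss$states
  if (alive_only) s <- filter(s, !.data$is_death)
  s$state
}

#' Map affected transition types to transition pairs
#'
#' Derives, from the state flags, the (from, to) pairs belonging to each of
#' the six transition types whose probabilities hypertension prevalence is
#' assumed to modify: incidence of CVD, of cognitive impairment and of
#' disability, recovery from disability, and CVD and non-CVD death.
#'
#' @param ss A [state_space].
#' @return A tibble with columns `transition_type`, `from_state`, `to_state`.
#' @export
affected_transition_map <- function(ss) {
  st <- ss$states
  tr <- filter(ss$transitions, .data$from_state != .data$to_state)
  f <- st %>% select(from_state = "state", f_cvd = "has_cvd", f_ci = "has_ci",
                     f_dis = "has_disability", f_death = "is_death")
  t <- st %>% select(to_state = "state", t_cvd = "has_cvd", t_ci = "has_ci",
                     t_dis = "has_disability", t_death = "is_death",
                     t_cause = "death_cause")
  tr %>%
    left_join(f, by = "from_state") %>%
    left_join(t, by = "to_state") %>%
    mutate(transition_type = dplyr::case_when(
      .data$t_death & .data$t_cause == "CVD" ~ "cvd_death",
      .data$t_death ~ "noncvd_death",
      .data$t_cvd & !.data$f_cvd ~ "cvd_incidence",
      .data$t_ci & !.data$f_ci ~ "ci_incidence",
      .data$t_dis & !.data$f_dis ~ "disability_incidence",
      !.data$t_dis & .data$f_dis ~ "disability_recovery",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$transition_type)) %>%
    select("transition_type", "from_state", "to_state") %>%
    arrange(.data$transition_type, .data$from_state)
}
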