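# fixtures built in code, shared across test files

# minimal space: one alive state and one death state
two_state_space <- function() {
  state_space(
    states = tibble::tibble(
      state = c("FREE", "NONCVD_DEATH"),
      has_cvd = FALSE, has_ci = FALSE, has_disability = FALSE,
      is_death = c(FALSE, TRUE),
      death_cause = c("none", "non-CVD")
    ),
    transitions = tibble::tibble(from_state = "FREE", to_state = "NONCVD_DEATH")
  )
}

# time-invariant 2-state table with death probability q at every age
two_state_tt <- function(q, ages) {
  tidyr::expand_grid(sex = c("men", "women"), age = ages) |>
    dplyr::mutate(from_state = "FREE") |>
    tidyr::expand_grid(tibble::tibble(to_state = c("FREE", "NONCVD_DEATH"))) |>
    dplyr::mutate(probability = ifelse(to_state == "NONCVD_DEATH", q, 1 - q))
}

# n persons of each sex in `state` at every age
uniform_pop <- function(ages, state = "FREE", n = 1000) {
  tidyr::expand_grid(sex = c("men", "women"), age = ages) |>
    dplyr::mutate(state = state, count = n)
}

# identity table (everyone stays) for a state space
identity_tt <- function(ss, ages) {
  alive <- states_of(ss, alive_only = TRUE)
  tidyr::expand_grid(sex = c("men", "women"), age = ages, from_state = alive) |>
    dplyr::mutate(to_state = from_state, probability = 1)
}

# random valid transition table on a state space: gamma weights normalised
# over each row's allowed destinations
random_transition_table <- function(ss, ages, seed = 1) {
  set.seed(seed)
  alive <- states_of(ss, alive_only = TRUE)
  rows <- tidyr::expand_grid(sex = c("men", "women"), age = ages,
                             ss$transitions) |>
    dplyr::filter(from_state %in% alive) |>
    dplyr::mutate(w = stats::rgamma(dplyr::n(), shape = 1)) |>
    dplyr::group_by(sex, age, from_state) |>
    dplyr::mutate(probability = w / sum(w)) |>
    dplyr::ungroup() |>
    dplyr::select(sex, age, from_state, to_state, probability)
  rows
}

# three alive states (disease-free, CVD, disability) plus one death state,
# used for the individual-level microsimulation oracle
oracle_space <- function() {
  state_space(
    states = tibble::tibble(
      state = c("FREE", "CVD", "DIS", "NONCVD_DEATH"),
      has_cvd = c(FALSE, TRUE, FALSE, FALSE),
      has_ci = FALSE,
      has_disability = c(FALSE, FALSE, TRUE, FALSE),
      is_death = c(FALSE, FALSE, FALSE, TRUE),
      death_cause = c("none", "none", "none", "non-CVD")
    ),
    transitions = dplyr::bind_rows(
      tibble::tibble(from_state = c("FREE", "FREE", "DIS"),
                     to_state = c("CVD", "DIS", "FREE")),
      tidyr::expand_grid(from_state = c("FREE", "CVD", "DIS"),
                         to_state = "NONCVD_DEATH")
    )
  )
}

# individual-level microsimulation: integer persons, multinomial draws per
# (age, state) cell and year; same conventions as the cohort engine
# (transition, then age with a closed top interval; no entrants)
microsimulate <- function(pop0, tt, years, ss, ages, seed = 1) {
  set.seed(seed)
  states <- states_of(ss)
  P <- bamsim:::tt_to_array(tt, ss, ages)
  counts <- bamsim:::pop_to_array(pop0, ss, ages)
  sexes <- dimnames(counts)[[1]]
  out <- vector("list", years)
  for (t in seq_len(years)) {
    landed <- array(0, dim = dim(counts), dimnames = dimnames(counts))
    for (sx in seq_along(sexes)) {
      for (a in seq_along(ages)) {
        for (s in seq_along(states)) {
          n <- counts[sx, a, s]
          if (n > 0) {
            landed[sx, a, ] <- landed[sx, a, ] +
              as.vector(rmultinom(1, n, P[sx, a, s, ]))
          }
        }
      }
    }
    aged <- array(0, dim = dim(counts), dimnames = dimnames(counts))
    n_age <- length(ages)
    aged[, 2:n_age, ] <- landed[, 1:(n_age - 1), ]
    aged[, n_age, ] <- aged[, n_age, ] + landed[, n_age, ]
    counts <- aged
    out[[t]] <- counts
  }
  out
}

# toy bundle whose observed prevalence is flat, so the constant scenario's
# path coincides with baseline's and all impact fractions vanish
flat_prevalence_toy <- function() {
  toy <- generate_toy_example()
  toy$prevalence <- toy$prevalence |>
    dplyr::group_by(age_group, sex) |>
    dplyr::mutate(prevalence = prevalence[year == max(year)]) |>
    dplyr::ungroup()
  toy
}

# a trajectory where everyone sits in `state` at every age with death prob q
flat_mortality_traj <- function(q, state = "FREE", ages = 65:100, n = 1000,
                                years = c(2020, 2021), mix = NULL) {
  ss <- default_state_space()
  alive <- states_of(ss, alive_only = TRUE)
  tt <- tidyr::expand_grid(sex = c("men", "women"), age = ages,
                           from_state = alive) |>
    tidyr::expand_grid(tibble::tibble(to_state_kind = c("stay", "die"))) |>
    dplyr::mutate(to_state = ifelse(to_state_kind == "stay", from_state, "NONCVD_DEATH"),
                  probability = ifelse(to_state_kind == "stay", 1 - q, q)) |>
    dplyr::select(sex, age, from_state, to_state, probability)
  pop <- if (is.null(mix)) {
    uniform_pop(ages, state, n)
  } else {
    purrr::imap_dfr(mix, function(cnt, st) uniform_pop(ages, st, cnt))
  }
  project(pop, tt, NULL, years = years, ss = ss, ages = ages)
}

# smaller miniature for the Monte Carlo tests: fewer ages, shorter horizon
psa_toy <- function() {
  toy <- generate_toy_example()
  keep_ages <- 65:69
  toy$population <- dplyr::filter(toy$population, age %in% keep_ages)
  toy$transition_table <- dplyr::filter(toy$transition_table, age %in% keep_ages)
  toy$prevalence <- dplyr::filter(toy$prevalence, age_group == "65-69")
  toy$rr <- dplyr::filter(toy$rr, age_group == "65-69")
  toy$mortality <- dplyr::filter(toy$mortality, age_group == "65-69")
  toy$run_args <- list(years = c(2013, 2015), since = 2014, min_age = 65,
                       report_years = 2015, target_year = 2017,
                       reduction_fraction = 0.5,
                       scenarios = c("baseline", "optimistic"))
  toy
}
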