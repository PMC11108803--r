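test_that("default space has ten states with the documented structure", {
  ss <- default_state_space()
  expect_equal(nrow(ss$states), 10)
  expect_equal(sum(!ss$states$is_death), 8)
  expect_equal(sum(ss$states$is_death), 2)
  expect_equal(ss$entrant_state, "FREE")

  dem <- dplyr::filter(ss$states, state == "DEM")
  expect_true(dem$has_ci && dem$has_disability && dem$is_dementia)
  # dementia flag is exactly the coexistence of cognitive impairment and disability
  expect_equal(ss$states$is_dementia,
               ss$states$has_ci & ss$states$has_disability)

  # death states absorbing
  expect_false(any(ss$transitions$from_state %in% c("CVD_DEATH", "NONCVD_DEATH")))
  # every alive state reaches both death states
  alive <- states_of(ss, alive_only = TRUE)
  for (d in c("CVD_DEATH", "NONCVD_DEATH")) {
    reached <- ss$transitions$from_state[ss$transitions$to_state == d]
    expect_setequal(reached, alive)
  }
})

test_that("default transition diagram respects irreversibility rules", {
  ss <- default_state_space()
  flags <- ss$states
  tr <- dplyr::filter(ss$transitions, from_state != to_state) |>
    dplyr::left_join(flags, by = c(from_state = "state")) |>
    dplyr::left_join(flags, by = c(to_state = "state"), suffix = c("_f", "_t"))
  alive_tr <- dplyr::filter(tr, !is_death_t)
  # CVD and cognitive impairment are never lost
  expect_false(any(alive_tr$has_cvd_f & !alive_tr$has_cvd_t))
  expect_false(any(alive_tr$has_ci_f & !alive_tr$has_ci_t))
  # disability recovery only while cognitively intact
  rec <- dplyr::filter(alive_tr, has_disability_f & !has_disability_t)
  expect_false(any(rec$has_ci_f))
  # at most one condition acquired per year
  gains <- with(alive_tr,
                (has_cvd_t & !has_cvd_f) + (has_ci_t & !has_ci_f) +
                  (has_disability_t & !has_disability_f))
  expect_true(all(gains <= 1))
  # hence no direct move from disease-free into dementia
  expect_false(any(alive_tr$from_state == "FREE" & alive_tr$is_dementia_t))
  # by default there is no exit from dementia except to the death states
  dem_exits <- dplyr::filter(tr, is_dementia_f)
  expect_true(all(dem_exits$is_death_t))
})

test_that("dementia states regain a CVD exit when the option is enabled", {
  ss <- default_state_space(allow_cvd_from_dementia = TRUE)
  expect_true(any(ss$transitions$from_state == "DEM" &
                    ss$transitions$to_state == "CVD_DEM"))
})

test_that("affected transition map covers exactly the six modified types", {
  map <- affected_transition_map(default_state_space())
  expect_setequal(unique(map$transition_type),
                  c("cvd_incidence", "ci_incidence", "disability_incidence",
                    "disability_recovery", "cvd_death", "noncvd_death"))
  expect_equal(sum(map$transition_type == "cvd_death"), 8)
  expect_equal(sum(map$transition_type == "noncvd_death"), 8)
  expect_equal(sum(map$transition_type == "disability_recovery"), 2)
  # dementia entries are classified by the condition they add
  expect_true(dplyr::filter(map, from_state == "CI", to_state == "DEM")$transition_type ==
                "disability_incidence")
  expect_true(dplyr::filter(map, from_state == "DIS", to_state == "DEM")$transition_type ==
                "ci_incidence")
})

test_that("constructor rejects malformed spaces", {
  flags <- tibble::tibble(
    state = c("FREE", "SICK", "DEAD"),
    has_cvd = c(FALSE, TRUE, FALSE), has_ci = FALSE, has_disability = FALSE,
    is_death = c(FALSE, FALSE, TRUE), death_cause = c("none", "none", "non-CVD")
  )
  # missing death transition for SICK
  expect_error(
    state_space(flags, tibble::tibble(from_state = "FREE", to_state = "DEAD")),
    "death state")
  # transition out of a death state
  expect_error(
    state_space(flags, tibble::tibble(from_state = c("FREE", "SICK", "DEAD"),
                                      to_state = c("DEAD", "DEAD", "FREE"))),
    "absorbing")
  # two flag-free alive states -> ambiguous entrant
  flags2 <- dplyr::mutate(flags, has_cvd = FALSE)
  expect_error(
    state_space(flags2, tibble::tibble(from_state = c("FREE", "SICK"),
                                       to_state = "DEAD")),
    "disease-free")
})
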