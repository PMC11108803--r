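test_that("the attributable fraction follows Levin's formula", {
  expect_equal(parf(0, 3), 0)
  expect_equal(parf(0.7, 1), 0)
  expect_equal(parf(0.3, 2), 0.3 / 1.3, tolerance = 1e-12)
  expect_error(parf(0.3, 0), "positive")
  expect_error(parf(-0.1, 2), "\\[0, 1\\]")
})

test_that("the impact fraction has the right limits and worked values", {
  expect_equal(delta_parf(0.4, 0.4, 1.7), 0)
  # full elimination reduces to the attributable fraction
  set.seed(1)
  p <- runif(200)
  rr <- exp(rnorm(200, 0, 0.5))
  expect_equal(delta_parf(p, 0, rr), parf(p, rr), tolerance = 1e-12)
  expect_equal(delta_parf(0.4, 0.2, 1.5), 0.2 * 0.5 / 1.2, tolerance = 1e-12)
  # protective exposure on a recovery transition: prevalence fall -> negative delta
  expect_equal(delta_parf(0.4, 0.2, 0.8), 0.2 * (-0.2) / (1 + 0.4 * (-0.2)),
               tolerance = 1e-12)
})

test_that("parf is monotone in prevalence and relative risk", {
  p_grid <- seq(0.05, 0.95, by = 0.05)
  vals <- parf(p_grid, 2)
  expect_true(all(diff(vals) > 0))
  rr_grid <- seq(1.1, 5, by = 0.1)
  vals <- parf(0.3, rr_grid)
  expect_true(all(diff(vals) > 0))
})

test_that("zero impact fractions leave the transition table untouched", {
  ss <- default_state_space()
  tt <- random_transition_table(ss, ages = 66:68, seed = 11) |>
    tidyr::expand_grid(year = 2016:2017) |>
    dplyr::select(year, sex, age, from_state, to_state, probability)
  deltas <- tidyr::expand_grid(
    year = 2016:2017, age_group = "65-69", sex = c("men", "women"),
    transition_type = unique(affected_transition_map(ss)$transition_type)) |>
    dplyr::mutate(delta = 0)
  out <- apply_delta_parf(tt, deltas, ss = ss)
  expect_identical(
    dplyr::arrange(out, year, sex, age, from_state, to_state)$probability,
    dplyr::arrange(tt, year, sex, age, from_state, to_state)$probability)
})

test_that("impact fractions scale mapped cells and the stay row absorbs the shift", {
  ss <- default_state_space()
  tt <- tibble::tibble(
    year = 2020, sex = "men", age = 70,
    from_state = "FREE",
    to_state = c("CVD", "CI", "DIS", "CVD_DEATH", "NONCVD_DEATH"),
    probability = c(0.02, 0.03, 0.04, 0.01, 0.02)) |>
    complete_stay_probability(ss)
  deltas <- tibble::tibble(year = 2020, age_group = "70-74", sex = "men",
                           transition_type = "cvd_incidence", delta = 0.1)
  out <- apply_delta_parf(tt, deltas, ss = ss)
  get <- function(to) dplyr::filter(out, to_state == to)$probability
  expect_equal(get("CVD"), 0.018, tolerance = 1e-15)
  expect_equal(get("FREE"), 0.88 + 0.002, tolerance = 1e-15)
  expect_equal(get("CI"), 0.03)
  expect_equal(sum(out$probability), 1, tolerance = 1e-12)

  # a recovery transition with negative delta becomes more likely
  tt_r <- tibble::tibble(
    year = 2020, sex = "men", age = 70, from_state = "DIS",
    to_state = c("FREE", "CVD_DEATH", "NONCVD_DEATH"),
    probability = c(0.10, 0.01, 0.02)) |>
    complete_stay_probability(ss)
  d <- delta_parf(0.4, 0.2, 0.8)
  deltas_r <- tibble::tibble(year = 2020, age_group = "70-74", sex = "men",
                             transition_type = "disability_recovery", delta = d)
  out_r <- apply_delta_parf(tt_r, deltas_r, ss = ss)
  expect_equal(dplyr::filter(out_r, to_state == "FREE")$probability,
               0.10 * (1 - d), tolerance = 1e-12)
  expect_gt(dplyr::filter(out_r, to_state == "FREE")$probability, 0.10)
  expect_equal(0.10 * (1 - d), 0.10 * 1.0434783, tolerance = 1e-6)
})

test_that("an adjustment that exhausts the stay probability is an error", {
  ss <- default_state_space()
  tt <- tibble::tibble(
    year = 2020, sex = "men", age = 70, from_state = "FREE",
    to_state = c("CVD", "CVD_DEATH", "NONCVD_DEATH"),
    probability = c(0.9, 0.04, 0.05)) |>
    complete_stay_probability(ss)
  deltas <- tibble::tibble(year = 2020, age_group = "70-74", sex = "men",
                           transition_type = "cvd_incidence", delta = -0.5)
  expect_error(apply_delta_parf(tt, deltas, ss = ss), "stay probability")
})
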