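make_series <- function(beta, r0 = 0.01, years = 2007:2016, exposure = 1e8,
                        noise = FALSE) {
  tibble::tibble(age_group = "65-69", sex = "men", cause = "CVD",
                 year = years,
                 exposure = exposure,
                 expected = r0 * exp(beta * (years - max(years))) * exposure) |>
    dplyr::mutate(deaths = if (noise) rpois(length(years), expected) else expected) |>
    dplyr::select(-expected)
}

test_that("a noiseless log-linear series returns its slope and rate", {
  fit <- fit_loglinear_trend(make_series(beta = -0.02))
  expect_equal(fit$slope, -0.02, tolerance = 1e-3)
  expect_equal(exp(fit$intercept), 0.01, tolerance = 1e-6)
  expect_equal(attr(fit, "reference_year"), 2016)

  flat <- fit_loglinear_trend(make_series(beta = 0))
  expect_equal(flat$slope, 0, tolerance = 1e-9)
})

test_that("the observation window restricts the fitted years", {
  s <- dplyr::bind_rows(make_series(-0.02),
                        make_series(-0.10, years = 2000:2006))
  fit <- fit_loglinear_trend(s, window = c(2007, 2016))
  expect_equal(attr(fit, "window"), c(2007, 2016))
  expect_equal(fit$slope, -0.02, tolerance = 1e-3)
})

test_that("an all-zero stratum warns and freezes its trend", {
  s <- make_series(-0.02) |> dplyr::mutate(deaths = 0)
  expect_warning(fit <- fit_loglinear_trend(s), "no deaths")
  expect_equal(fit$slope, 0)
})

test_that("rate projection follows the scenario multiplier closed form", {
  fit <- fit_loglinear_trend(make_series(beta = -0.01))
  frozen <- project_rates(fit, horizon = 2030, slope_multiplier = 0)
  expect_equal(length(unique(frozen$rate)), 1)
  expect_equal(unique(frozen$rate),
               dplyr::filter(frozen, year == 2016)$rate)

  doubled <- project_rates(fit, horizon = 2026, slope_multiplier = 2)
  r16 <- dplyr::filter(doubled, year == 2016)$rate
  r26 <- dplyr::filter(doubled, year == 2026)$rate
  expect_equal(r26 / r16, exp(2 * fit$slope * 10), tolerance = 1e-9)
  expect_equal(r26 / r16, exp(-0.2), tolerance = 1e-3)

  expect_error(project_rates(fit, horizon = 2030, slope_multiplier = -1),
               "non-negative")

  # monotone: a larger multiplier on a declining trend lowers every future rate
  rates <- lapply(c(0, 0.5, 1, 1.5, 2), function(m)
    dplyr::filter(project_rates(fit, 2040, m), year > 2016)$rate)
  for (k in 2:5) expect_true(all(rates[[k]] < rates[[k - 1]]))
})

test_that("the seven sensitivity scenarios span no-improvement to doubling", {
  sc <- mortality_scenarios()
  expect_equal(nrow(sc), 7)
  expect_equal(sc$slope_multiplier, c(0, 1/3, 2/3, 1, 4/3, 5/3, 2))
  expect_equal(sc$slope_multiplier[sc$label == "central"], 1)
})

test_that("death multipliers are rate ratios anchored at the base year", {
  fit <- fit_loglinear_trend(make_series(beta = log(0.5) / 10))
  proj <- project_rates(fit, horizon = 2026)
  mult <- death_tp_multipliers(proj, base_year = 2016)
  expect_equal(dplyr::filter(mult, year == 2016)$multiplier, 1, tolerance = 1e-12)
  # the rate halves over ten years, so the multiplier does too
  expect_equal(dplyr::filter(mult, year == 2026)$multiplier, 0.5, tolerance = 1e-6)
  expect_error(death_tp_multipliers(dplyr::mutate(proj, rate = 0), 2016), "zero")
})

test_that("scaling death transitions keeps rows stochastic via the stay probability", {
  ss <- default_state_space()
  tt <- random_transition_table(ss, ages = 66:68, seed = 5)
  mult <- tidyr::expand_grid(year = 2016:2018, age_group = "65-69",
                             sex = c("men", "women"), cause = c("CVD", "non-CVD")) |>
    dplyr::mutate(multiplier = ifelse(year == 2016, 1, 0.5))
  out <- apply_death_multipliers(tt, mult, ss)
  expect_equal(nrow(validate_transition_table(out, ss)), 0)

  before <- dplyr::filter(tt, from_state == "FREE", to_state == "CVD_DEATH",
                          sex == "men", age == 66)$probability
  after <- dplyr::filter(out, year == 2017, from_state == "FREE",
                         to_state == "CVD_DEATH", sex == "men", age == 66)$probability
  expect_equal(after, before * 0.5, tolerance = 1e-12)
  # base year untouched
  base <- dplyr::filter(out, year == 2016, from_state == "FREE",
                        to_state == "CVD_DEATH", sex == "men", age == 66)$probability
  expect_equal(base, before, tolerance = 1e-15)
})
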