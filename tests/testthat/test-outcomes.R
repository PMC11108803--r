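test_that("incident cases count flag acquisitions among the old enough", {
  ss <- default_state_space()
  ages <- 64:66
  # 1000 persons in CI per age; CI -> DEM with probability 0.05
  tt <- identity_tt(ss, ages) |>
    dplyr::mutate(probability = ifelse(from_state == "CI", 0.95, probability)) |>
    dplyr::bind_rows(
      tidyr::expand_grid(sex = c("men", "women"), age = ages) |>
        dplyr::mutate(from_state = "CI", to_state = "DEM", probability = 0.05))
  pop <- uniform_pop(ages, "CI", 1000)
  traj <- project(pop, tt, NULL, years = c(2020, 2020), ss = ss, ages = ages)

  dem <- incident_cases(traj, "dementia", min_age = 65)
  # ages 65 and 66 qualify (age at transition), both sexes: 2 ages x 50 x 2
  expect_equal(sum(dem$cases), 2 * 2 * 50)
  # entering dementia from cognitive impairment also newly acquires disability
  dis <- incident_cases(traj, "disability", min_age = 65)
  expect_equal(sum(dis$cases), 2 * 2 * 50)
  # nobody moves at all -> zero cases
  traj0 <- project(pop, identity_tt(ss, ages), NULL, years = c(2020, 2020),
                   ss = ss, ages = ages)
  expect_equal(sum(incident_cases(traj0, "dementia")$cases), 0)
  expect_error(incident_cases(traj, "obesity"), "must be one of")
})

test_that("a move from disability into dementia is not a disability incident", {
  ss <- default_state_space()
  ages <- 70:71
  tt <- identity_tt(ss, ages) |>
    dplyr::mutate(probability = ifelse(from_state == "DIS", 0.9, probability)) |>
    dplyr::bind_rows(
      tidyr::expand_grid(sex = c("men", "women"), age = ages) |>
        dplyr::mutate(from_state = "DIS", to_state = "DEM", probability = 0.1))
  pop <- uniform_pop(ages, "DIS", 100)
  traj <- project(pop, tt, NULL, years = c(2020, 2020), ss = ss, ages = ages)
  expect_equal(sum(incident_cases(traj, "dementia")$cases), 2 * 2 * 10)
  expect_equal(sum(incident_cases(traj, "disability")$cases), 0)
})

test_that("scenario differences accumulate baseline minus counterfactual", {
  traj_hi <- flat_mortality_traj(0.10, years = c(2015, 2019))
  traj_lo <- flat_mortality_traj(0.08, years = c(2015, 2019))
  d <- scenario_difference(traj_lo, traj_hi, since = 2015)
  all_deaths <- dplyr::filter(d, sex == "all", measure == "deaths")
  expect_true(all(diff(all_deaths$avoided) > 0))  # fewer deaths each year
  # identical trajectories -> exact zeros
  d0 <- scenario_difference(traj_hi, traj_hi, since = 2015)
  expect_true(all(d0$avoided == 0))
  # per-100k consistency with its denominator
  expect_equal(d$avoided_per_100k * d$cumulative_person_years / 1e5,
               d$avoided, tolerance = 1e-9)
  # mismatched year ranges are refused
  short <- flat_mortality_traj(0.1, years = c(2015, 2018))
  expect_error(scenario_difference(short, traj_hi), "year ranges")
})

test_that("constructed per-year gaps cumulate as hand-computed", {
  traj_a <- flat_mortality_traj(0.10, ages = 70, n = 1000, years = c(2015, 2017))
  traj_b <- flat_mortality_traj(0.05, ages = 70, n = 1000, years = c(2015, 2017))
  d <- scenario_difference(traj_b, traj_a, since = 2015)
  got <- dplyr::filter(d, sex == "all", measure == "deaths")$avoided
  # per sex: year1 100 vs 50; year2 90 vs 47.5; year3 81 vs 45.125
  per_sex <- cumsum(c(100 - 50, 90 - 47.5, 81 - 45.125))
  expect_equal(got, 2 * per_sex, tolerance = 1e-9)
})

test_that("life expectancy matches the geometric closed form under constant hazard", {
  q <- 0.5
  traj <- flat_mortality_traj(q)
  le <- life_expectancy_at_65(traj, 2020, "both")
  # sum l(a)(1 - q/2) for geometric survival, truncation < 1e-9 at q = 0.5
  expect_equal(le, (1 - q / 2) / q, tolerance = 1e-6)
  # sex-specific equals pooled here by symmetry
  expect_equal(life_expectancy_at_65(traj, 2020, "men"), le, tolerance = 1e-12)
})

test_that("certain death in the first year leaves half a person-year", {
  traj <- flat_mortality_traj(1)
  expect_equal(life_expectancy_at_65(traj, 2020, "both"), 0.5, tolerance = 1e-12)
})

test_that("uniformly higher death probabilities lower life expectancy", {
  le1 <- life_expectancy_at_65(flat_mortality_traj(0.10), 2020)
  le2 <- life_expectancy_at_65(flat_mortality_traj(0.12), 2020)
  expect_lt(le2, le1)
})

test_that("a zero top-age death probability is an explicit error", {
  ss <- default_state_space()
  traj <- flat_mortality_traj(0)  # nobody ever dies
  expect_error(life_expectancy_at_65(traj, 2020), "top age")
})

test_that("Sullivan weighting reproduces its identities", {
  # everyone healthy: HLE = LE
  traj <- flat_mortality_traj(0.2, state = "FREE")
  le <- life_expectancy_at_65(traj, 2020)
  expect_equal(healthy_life_expectancy_at_65(traj, 2020), le, tolerance = 1e-12)
  # everyone with CVD: HLE = 0
  traj_cvd <- flat_mortality_traj(0.2, state = "CVD")
  expect_equal(healthy_life_expectancy_at_65(traj_cvd, 2020), 0)
  # 50% healthy at every age: HLE = LE / 2 (Sullivan linearity)
  traj_mix <- flat_mortality_traj(0.2, mix = c(FREE = 500, CVD = 500))
  expect_equal(healthy_life_expectancy_at_65(traj_mix, 2020),
               life_expectancy_at_65(traj_mix, 2020) / 2, tolerance = 1e-9)
  # cognitive impairment alone is healthy under the default definition
  traj_ci <- flat_mortality_traj(0.2, state = "CI")
  expect_equal(healthy_life_expectancy_at_65(traj_ci, 2020),
               life_expectancy_at_65(traj_ci, 2020), tolerance = 1e-12)
  # but not when the healthy-state set is overridden
  expect_equal(healthy_life_expectancy_at_65(traj_ci, 2020,
                                             healthy_states = "FREE"), 0)
})

test_that("life-years gained equal the hand-computed person-year differences", {
  traj_a <- flat_mortality_traj(0.10, ages = 70, n = 1000, years = c(2015, 2017))
  traj_b <- flat_mortality_traj(0.05, ages = 70, n = 1000, years = c(2015, 2017))
  lyg <- life_years_gained(traj_b, traj_a, since = 2015)
  got <- dplyr::filter(lyg, sex == "all")$life_years_gained
  py_a <- c((1000 + 900) / 2, (900 + 810) / 2, (810 + 729) / 2)
  py_b <- c((1000 + 950) / 2, (950 + 902.5) / 2, (902.5 + 857.375) / 2)
  expect_equal(got, 2 * cumsum(py_b - py_a), tolerance = 1e-9)
  # identical runs gain nothing; lower mortality gains monotonically
  expect_true(all(dplyr::filter(life_years_gained(traj_a, traj_a), sex == "all")$life_years_gained == 0))
  expect_true(all(diff(got) > 0))
})

test_that("person-year composition partitions into the four categories", {
  traj <- flat_mortality_traj(0.1, mix = c(FREE = 250, CVD = 250, DIS = 250, DEM = 250))
  comp <- life_year_composition(traj)
  expect_setequal(unique(comp$category), c("healthy", "cvd", "disability", "dementia"))
  sums <- comp |> dplyr::group_by(year) |> dplyr::summarise(s = sum(percent))
  expect_equal(sums$s, rep(100, nrow(sums)), tolerance = 1e-6)
  expect_true(all(comp$percent >= 0 & comp$percent <= 100))
})
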