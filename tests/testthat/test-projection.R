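test_that("identity transitions shift ages by one and hold the top age", {
  ss <- default_state_space()
  ages <- 98:100
  pop <- uniform_pop(ages, "FREE", 100)
  res <- step_year(pop, identity_tt(ss, ages), ss = ss, ages = ages)
  out <- res$population |> dplyr::filter(state == "FREE", sex == "men")
  expect_equal(out$count[out$age == 98], 0)
  expect_equal(out$count[out$age == 99], 100)
  expect_equal(out$count[out$age == 100], 200)  # 99s aged up + 100s held
  expect_true(all(res$flows$count == 0))
})

test_that("an all-to-death year empties the alive states and books the flows", {
  ss <- two_state_space()
  ages <- 65:70
  pop <- uniform_pop(ages, "FREE", 50)
  res <- step_year(pop, two_state_tt(1, ages), ss = ss, ages = ages)
  alive <- dplyr::filter(res$population, state == "FREE")
  expect_equal(sum(alive$count), 0)
  expect_equal(sum(res$flows$count), sum(pop$count))
})

test_that("a 10% death probability moves exactly 10% into the death flow", {
  ss <- two_state_space()
  pop <- tibble::tibble(sex = "men", age = 70, state = "FREE", count = 1000)
  res <- step_year(pop, two_state_tt(0.1, 70), ss = ss, ages = 70)
  expect_equal(sum(res$population$count[res$population$state == "FREE"]), 900)
  expect_equal(sum(res$flows$count), 100)
})

test_that("entrants join the disease-free state at the youngest age after ageing", {
  ss <- default_state_space()
  ages <- 35:37
  pop <- uniform_pop(ages, "CVD", 10)
  res <- step_year(pop, identity_tt(ss, ages), entrants = c(men = 5, women = 7),
                   ss = ss, ages = ages)
  ent <- dplyr::filter(res$population, age == 35, state == "FREE")
  expect_equal(ent$count[ent$sex == "men"], 5)
  expect_equal(ent$count[ent$sex == "women"], 7)
  # entrants did not transition in their entry year: no flows out of FREE at 35
  expect_true(all(dplyr::filter(res$flows, age == 35, from_state == "FREE")$count == 0))
})

test_that("negative input counts are rejected as corrupt state", {
  ss <- two_state_space()
  pop <- tibble::tibble(sex = "men", age = 70, state = "FREE", count = -1)
  expect_error(step_year(pop, two_state_tt(0.1, 70), ss = ss, ages = 70),
               "negative")
})

test_that("constant-hazard survival follows the closed form (1-q)^t", {
  ss <- two_state_space()
  q <- 0.07
  n0 <- 1234
  ages <- 60:80
  pop <- tibble::tibble(sex = "men", age = 60, state = "FREE", count = n0)
  traj <- project(pop, two_state_tt(q, ages), entrants = NULL,
                  years = c(2000, 2009), ss = ss, ages = ages)
  alive <- traj$population |>
    dplyr::filter(state == "FREE") |>
    dplyr::group_by(year) |>
    dplyr::summarise(n = sum(count))
  expect_equal(alive$n, n0 * (1 - q)^(alive$year - 2000), tolerance = 1e-12)
})

test_that("projection conserves persons: inflows equal outflows plus stock", {
  ss <- default_state_space()
  ages <- 60:70
  for (seed in 1:3) {
    tt <- random_transition_table(ss, ages, seed = seed)
    pop <- uniform_pop(ages, "FREE", 500) |>
      dplyr::bind_rows(uniform_pop(ages, "CVD", 100))
    ent <- tidyr::expand_grid(year = 2010:2019, sex = c("men", "women")) |>
      dplyr::mutate(count = 50)
    traj <- project(pop, tt, ent, years = c(2010, 2019), ss = ss, ages = ages)
    cons <- conservation_summary(traj)
    expect_lt(max(abs(cons$residual) / cons$alive), 1e-6)
    # flows out of each cell sum to the cell's count (stay flow is implicit)
    dead <- c("CVD_DEATH", "NONCVD_DEATH")
    total_deaths <- sum(dplyr::filter(traj$flows, to_state %in% dead)$count)
    final_alive <- traj$population |>
      dplyr::filter(year == 2020, !state %in% dead) |>
      dplyr::pull(count) |> sum()
    expect_equal(final_alive + total_deaths,
                 sum(pop$count) + sum(ent$count), tolerance = 1e-9)
  }
})

test_that("with age- and year-invariant transitions the engine equals matrix powers", {
  ss <- default_state_space()
  ages <- 50:60
  tt <- random_transition_table(ss, ages = 50, seed = 9) |>
    dplyr::select(-age) |>
    tidyr::expand_grid(age = ages) |>
    dplyr::select(sex, age, from_state, to_state, probability)
  # same matrix for both sexes: use the men's rows everywhere
  tt <- tt |>
    dplyr::filter(sex == "men") |>
    dplyr::select(-sex) |>
    tidyr::expand_grid(sex = c("men", "women")) |>
    dplyr::select(sex, age, from_state, to_state, probability)

  states <- states_of(ss)
  P <- matrix(0, 10, 10, dimnames = list(states, states))
  diag(P)[9:10] <- 1
  rows <- dplyr::filter(tt, sex == "men", age == 50)
  P[cbind(match(rows$from_state, states), match(rows$to_state, states))] <-
    rows$probability
  expect_equal(unname(rowSums(P)), rep(1, 10), tolerance = 1e-12)

  init <- uniform_pop(ages, "FREE", 10) |>
    dplyr::bind_rows(uniform_pop(ages, "DIS", 5))
  traj <- project(init, tt, NULL, years = c(2000, 2007), ss = ss, ages = ages)

  v <- setNames(rep(0, 10), states)
  v["FREE"] <- sum(init$count[init$state == "FREE"])
  v["DIS"] <- sum(init$count[init$state == "DIS"])
  for (t in 1:7) v <- as.vector(v %*% P) |> setNames(states)
  got <- traj$population |>
    dplyr::filter(year == 2007) |>
    dplyr::group_by(state) |>
    dplyr::summarise(n = sum(count))
  expect_equal(setNames(got$n, got$state)[states], v, tolerance = 1e-9)
})

test_that("missing years in inputs are reported by name", {
  ss <- two_state_space()
  pop <- tibble::tibble(sex = "men", age = 70, state = "FREE", count = 10)
  tt_y <- two_state_tt(0.1, 70:75) |> dplyr::mutate(year = 2010)
  expect_error(project(pop, tt_y, NULL, years = c(2010, 2012), ss = ss, ages = 70:75),
               "2011")
  ent <- tibble::tibble(year = 2010, sex = "men", count = 1)
  expect_error(project(pop, two_state_tt(0.1, 70:75), ent,
                       years = c(2010, 2012), ss = ss, ages = 70:75),
               "2011")
})
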