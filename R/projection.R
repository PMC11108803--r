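#' Cohort projection of a population through the state space
#'
#' The engine advances expected person counts (real-valued, not integers)
#' through the health states one calendar year at a time: transitions are
#' applied first, every survivor then ages by one year (survivors at the top
#' modelled age remain there -- the top age interval is closed), and finally
#' the year's entrant cohort is added at the youngest modelled age in the
#' disease-free state, so entrants do not transition in their entry year.
#'
#' @name projection
NULL

# --- array internals --------------------------------------------------------

pop_to_array <- function(pop, ss, ages, sexes = SEXES) {
  states <- states_of(ss)
  A <- array(0, dim = c(length(sexes), length(ages), length(states)),
             dimnames = list(sexes, ages, states))
  i <- cbind(match(pop$sex, sexes), match(pop$age, ages), match(pop$state, states))
  if (anyNA(i)) abort("population has a sex, age or state outside the model")
  A[i] <- A[i] + pop$count
  A
}

array_to_pop <- function(A) {
  dn <- dimnames(A)
  out <- tidyr::expand_grid(state = dn[[3]], age = as.integer(dn[[2]]), sex = dn[[1]])
  # expand_grid varies the last column fastest; as.vector(A) varies sex fastest
  out$count <- as.vector(A)
  select(out, "sex", "age", "state", "count") %>%
    arrange(.data$sex, .data$age, .data$state)
}

# one simulated year on dense arrays; returns new counts and the flow array
step_arrays <- function(counts, P, entrants_by_sex, entrant_state_idx) {
  d <- dim(counts)
  flows <- P * as.vector(counts)            # flows[sex, age, from, to]
  landed <- apply(flows, c(1, 2, 4), sum)   # counts by destination, pre-ageing
  aged <- array(0, dim = d, dimnames = dimnames(counts))
  n_age <- d[2]
  if (n_age > 1) aged[, 2:n_age, ] <- landed[, 1:(n_age - 1), , drop = FALSE]
  aged[, n_age, ] <- aged[, n_age, ] + landed[, n_age, ]  # closed top interval
  aged[, 1, entrant_state_idx] <- aged[, 1, entrant_state_idx] + entrants_by_sex
  list(counts = aged, flows = flows)
}

# --- user-facing single step ------------------------------------------------

#' Advance a population by one year
#'
#' @param pop Population at the start of the year: a data frame with columns
#'   `sex`, `age`, `state`, `count` (counts are non-negative expected
#'   persons).
#' @param tt_slice Transition table for this year (no `year` column, or a
#'   single year).
#' @param entrants Named numeric vector of entrants per sex (default zero),
#'   added at the youngest modelled age in the disease-free state after
#'   transitions and ageing.
#' @param ss A [state_space].
#' @param ages Integer vector of modelled ages; defaults to the range of ages
#'   present in `pop`.
#' @return A list with `population` (start of the next year) and `flows`
#'   (tibble `sex`, `age`, `from_state`, `to_state`, `count` of persons who
#'   made each move during the year, indexed by age at the start of the
#'   year).
#' @export
step_year <- function(pop, tt_slice, entrants = NULL, ss = default_state_space(),
                      ages = NULL) {
  pop <- as_tibble(pop)
  check_columns(pop, c("sex", "age", "state", "count"), "population")
  check_sex(pop$sex, "population")
  if (any(pop$count < 0)) abort("population has negative counts: corrupt state")
  ages <- ages %||% seq(min(pop$age), max(pop$age))
  ent <- setNames(rep(0, length(SEXES)), SEXES)
  if (!is.null(entrants)) ent[names(entrants)] <- entrants

  counts <- pop_to_array(pop, ss, ages)
  P <- tt_to_array(tt_slice, ss, ages)
  res <- step_arrays(counts, P, ent[SEXES], match(ss$entrant_state, states_of(ss)))
  list(
    population = array_to_pop(res$counts),
    flows = flows_to_tibble(res$flows, ss)
  )
}

flows_to_tibble <- function(flows, ss) {
  dn <- dimnames(flows)
  keep <- ss$transitions
  out <- tidyr::expand_grid(to_state = dn[[4]], from_state = dn[[3]],
                            age = as.integer(dn[[2]]), sex = dn[[1]])
  out$count <- as.vector(flows)
  out %>%
    semi_join(keep, by = c("from_state", "to_state")) %>%
    filter(.data$from_state != .data$to_state) %>%
    select("sex", "age", "from_state", "to_state", "count") %>%
    arrange(.data$sex, .data$age, .data$from_state, .data$to_state)
}

# --- multi-year projection --------------------------------------------------

#' Project a population over calendar years
#'
#' Iterates [step_year()] from `years[1]` to `years[2]` inclusive. The
#' projection is deterministic given its inputs.
#'
#' @param pop0 Population at the start of `years[1]` (columns `sex`, `age`,
#'   `state`, `count`).
#' @param tt Transition table, either time-invariant (no `year` column) or
#'   covering every simulated year.
#' @param entrants Data frame `year`, `sex`, `count` of persons entering at
#'   the youngest modelled age each year, or `NULL` for none. Must cover
#'   every simulated year when supplied.
#' @param years Length-2 integer vector `c(start, end)` of calendar years to
#'   simulate.
#' @param ss A [state_space].
#' @param ages Modelled ages (defaults to the range in `pop0`).
#' @return A `population_trajectory`: a list with tibbles `population`
#'   (start-of-year counts for `start` through `end + 1`), `flows` (moves
#'   during each year) and `entrants`, carrying the state space as an
#'   attribute.
#' @export
project <- function(pop0, tt, entrants = NULL, years, ss = default_state_space(),
                    ages = NULL) {
  pop0 <- as_tibble(pop0)
  check_columns(pop0, c("sex", "age", "state", "count"), "pop0")
  if (any(pop0$count < 0)) abort("population has negative counts: corrupt state")
  stopifnot(length(years) == 2, years[2] >= years[1])
  yrs <- seq(years[1], years[2])
  ages <- ages %||% seq(min(pop0$age), max(pop0$age))

  ent_tbl <- tibble(year = integer(), sex = character(), count = numeric())
  if (!is.null(entrants)) {
    entrants <- as_tibble(entrants)
    check_columns(entrants, c("year", "sex", "count"), "entrants")
    missing_years <- setdiff(yrs, unique(entrants$year))
    if (length(missing_years) > 0) {
      abort(sprintf("entrants are missing year%s: %s",
                    if (length(missing_years) > 1) "s" else "",
                    paste(missing_years, collapse = ", ")))
    }
    ent_tbl <- filter(entrants, .data$year %in% yrs)
  }

  P_by_year <- tt_year_arrays(tt, ss, ages, yrs)
  counts <- pop_to_array(pop0, ss, ages)
  entrant_idx <- match(ss$entrant_state, states_of(ss))

  pops <- vector("list", length(yrs) + 1)
  flows <- vector("list", length(yrs))
  pops[[1]] <- array_to_pop(counts) %>% mutate(year = yrs[1], .before = 1)
  for (k in seq_along(yrs)) {
    ent <- setNames(rep(0, length(SEXES)), SEXES)
    if (nrow(ent_tbl) > 0) {
      e <- filter(ent_tbl, .data$year == yrs[k])
      ent[e$sex] <- e$count
    }
    res <- step_arrays(counts, P_by_year[[k]], ent[SEXES], entrant_idx)
    counts <- res$counts
    pops[[k + 1]] <- array_to_pop(counts) %>% mutate(year = yrs[k] + 1L, .before = 1)
    flows[[k]] <- flows_to_tibble(res$flows, ss) %>% mutate(year = yrs[k], .before = 1)
  }

  structure(
    list(
      population = bind_rows(pops),
      flows = bind_rows(flows),
      entrants = ent_tbl,
      years = yrs,
      ages = ages
    ),
    state_space = ss,
    class = "population_trajectory"
  )
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("<population_trajectory> years %d-%d, ages %d-%d, %d states\n",
              min(x$years), max(x$years), min(x$ages), max(x$ages),
              nrow(attr(x, "state_space")$states)))
  tot <- x$population %>%
    left_join(attr(x, "state_space")$states %>% select("state", "is_death"),
              by = "state") %>%
    filter(.data$year == min(.data$year) | .data$year == max(.data$year) + 0) %>%
    group_by(.data$year) %>%
    summarise(alive = sum(.data$count[!.data$is_death]), .groups = "drop")
  print(tot, ...)
  invisible(x)
}

#' Alive population, deaths and conservation summary of a trajectory
#'
#' Per simulated year: alive persons at the start, entrants, deaths during
#' the year, alive at the start of the next year, and the conservation
#' residual `alive(t+1) - (alive(t) + entrants(t) - deaths(t))`, which is
#' zero up to floating-point error for a valid engine.
#'
#' @param traj A `population_trajectory`.
#' @return A tibble per year.
#' @export
conservation_summary <- function(traj) {
  ss <- attr(traj, "state_space")
  dead_states <- states_of(ss)[ss$states$is_death]
  alive_by_year <- traj$population %>%
    filter(!.data$state %in% dead_states) %>%
    group_by(.data$year) %>%
    summarise(alive = sum(.data$count), .groups = "drop")
  deaths_by_year <- traj$flows %>%
    filter(.data$to_state %in% dead_states) %>%
    group_by(.data$year) %>%
    summarise(deaths = sum(.data$count), .groups = "drop")
  ent <- traj$entrants %>%
    group_by(.data$year) %>%
    summarise(entrants = sum(.data$count), .groups = "drop")
  tibble(year = traj$years) %>%
    left_join(alive_by_year, by = "year") %>%
    left_join(alive_by_year %>% mutate(year = .data$year - 1L) %>%
                rename(alive_next = "alive"), by = "year") %>%
    left_join(deaths_by_year, by = "year") %>%
    left_join(ent, by = "year") %>%
    mutate(across(c("deaths", "entrants"), ~tidyr::replace_na(.x, 0)),
           residual = .data$alive_next - (.data$alive + .data$entrants - .data$deaths))
}
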