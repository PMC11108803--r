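#' Diagnostic plots
#'
#' `autoplot()` methods for the main result types, built on ggplot2.
#'
#' @name bamsim_plots
NULL

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_area geom_hline
#'   geom_ribbon geom_pointrange facet_wrap labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot prevalence scenario paths
#'
#' @param prev Combined scenario prevalence table (e.g. the `$prevalence`
#'   element of a `scenario_comparison`).
#' @param sexes Which sexes to show.
#' @return A ggplot.
#' @export
plot_prevalence_scenarios <- function(prev, sexes = SEXES) {
  prev %>%
    filter(.data$sex %in% sexes) %>%
    ggplot(aes(x = .data$year, y = .data$prevalence, colour = .data$scenario)) +
    geom_line() +
    facet_wrap(~ .data$age_group + .data$sex) +
    labs(x = "year", y = "hypertension prevalence", colour = "scenario") +
    theme_minimal()
}

#' @rdname bamsim_plots
#' @param object A `population_trajectory`.
#' @param min_age Lower age bound for the plotted counts.
#' @param ... Unused.
#' @export
autoplot.population_trajectory <- function(object, min_age = 65, ...) {
  ss <- attr(object, "state_space")
  alive <- states_of(ss, alive_only = TRUE)
  object$population %>%
    filter(.data$state %in% alive, .data$age >= min_age) %>%
    group_by(.data$year, .data$state) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(state = factor(.data$state, levels = alive)) %>%
    ggplot(aes(x = .data$year, y = .data$count, fill = .data$state)) +
    geom_area() +
    labs(x = "year", y = sprintf("persons aged %d+", min_age), fill = "state") +
    theme_minimal()
}

#' @rdname bamsim_plots
#' @export
autoplot.scenario_comparison <- function(object, ...) {
  object$differences %>%
    filter(.data$sex == "all") %>%
    ggplot(aes(x = .data$year, y = .data$avoided, colour = .data$scenario)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_line() +
    facet_wrap(~ .data$measure, scales = "free_y") +
    labs(x = "year", colour = "scenario",
         y = "cumulative burden avoided vs baseline (persons)") +
    theme_minimal()
}

#' @rdname bamsim_plots
#' @export
autoplot.uncertainty_result <- function(object, ...) {
  object$cells %>%
    filter(.data$sex == "all") %>%
    ggplot(aes(x = factor(.data$year), y = .data$point, colour = .data$scenario)) +
    geom_pointrange(aes(ymin = .data$lower95, ymax = .data$upper95),
                    position = ggplot2::position_dodge(width = 0.5)) +
    facet_wrap(~ .data$measure, scales = "free_y") +
    labs(x = "year", y = "value (95% uncertainty interval)", colour = "scenario") +
    theme_minimal()
}
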