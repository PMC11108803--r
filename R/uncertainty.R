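#' Probabilistic sensitivity analysis
#'
#' Parameter uncertainty is propagated by Monte Carlo simulation: each
#' iteration draws one coherent set of inputs from specified distributions
#' (beta for transition probabilities and prevalence observations, lognormal
#' for relative risks, normal for fitted mortality slopes), reruns the whole
#' scenario comparison on the drawn set, and the 2.5th/97.5th percentiles
#' over iterations form the 95% uncertainty interval of every reported
#' output cell. The same draw is reused across scenarios within an
#' iteration (common random numbers), so scenario differences are
#' within-draw and their uncertainty reflects the scenarios rather than
#' sampling noise.
#'
#' @name uncertainty
NULL

#' Specify the input parameter distributions
#'
#' Beta distributions are parameterised by their mean (the point estimate)
#' and an effective sample size `n_eff` (`alpha = mean * n_eff`,
#' `beta = (1 - mean) * n_eff`); `n_eff = Inf` makes the distribution
#' degenerate at the point estimate. Relative risks are lognormal around the
#' point estimate with the table's `log_rr_se` (or an override). Mortality
#' trend slopes are normal around the central fit with the fitted standard
#' error (or an override; 0 disables).
#'
#' @param inputs Input bundle (see [run_comparison()]).
#' @param tp_n_eff Effective sample size behind each transition probability
#'   (default 1e4).
#' @param prevalence_n_eff Effective sample size behind each prevalence
#'   observation (default 1e4).
#' @param rr_se Override for the log-RR standard error (default: the
#'   bundle's `log_rr_se` column, or 0.05 when absent).
#' @param mortality_slope_sd Override for the slope standard deviation
#'   (default: the fitted per-stratum SE; 0 disables slope uncertainty).
#' @param mortality_window Passed to the central [fit_loglinear_trend()].
#' @param dirichlet_rows If `TRUE`, each transition-table row is drawn from
#'   a Dirichlet with concentration `probability * tp_n_eff`, guaranteeing
#'   row sums of one by construction, instead of independent betas with the
#'   stay probability absorbing the residual.
#' @return A `psa_distributions` object.
#' @export
psa_distributions <- function(inputs, tp_n_eff = 1e4, prevalence_n_eff = 1e4,
                              rr_se = NULL, mortality_slope_sd = NULL,
                              mortality_window = NULL, dirichlet_rows = FALSE) {
  if (tp_n_eff <= 0 || prevalence_n_eff <= 0) {
    abort("effective sample sizes must be positive (Inf for a degenerate distribution)")
  }
  if (!is.null(rr_se) && rr_se < 0) abort("rr_se must be non-negative")
  if (!is.null(mortality_slope_sd) && mortality_slope_sd < 0) {
    abort("mortality_slope_sd must be non-negative")
  }
  central_fit <- fit_loglinear_trend(inputs$mortality, mortality_window)
  structure(
    list(inputs = inputs, tp_n_eff = tp_n_eff,
         prevalence_n_eff = prevalence_n_eff, rr_se = rr_se,
         mortality_slope_sd = mortality_slope_sd,
         dirichlet_rows = dirichlet_rows, central_fit = central_fit),
    class = "psa_distributions"
  )
}

#' Draw one full input set
#'
#' Samples every uncertain input once, from the current RNG state, and
#' returns a bundle usable by [run_comparison()] (the perturbed mortality
#' fit is injected via its `mortality_fit` argument). Degenerate
#' distributions return the point estimates without consuming random
#' numbers.
#'
#' @param dists A [psa_distributions()] object.
#' @return A list with `inputs` (perturbed bundle) and `mortality_fit`.
#' @export
sample_draw <- function(dists) {
  stopifnot(inherits(dists, "psa_distributions"))
  inputs <- dists$inputs
  ss <- inputs$state_space %||% default_state_space()

  # transition probabilities
  if (is.finite(dists$tp_n_eff)) {
    inputs$transition_table <- draw_transition_table(
      inputs$transition_table, dists$tp_n_eff, dists$dirichlet_rows)
  }

  # relative risks: lognormal around the point estimate
  rr <- as_tibble(inputs$rr)
  se <- rep(dists$rr_se %||% rr$log_rr_se %||% 0.05, length.out = nrow(rr))
  if (any(se > 0)) {
    drawn <- rlnorm(nrow(rr), log(rr$rr), se)
    rr$rr <- ifelse(se > 0, drawn, rr$rr)
    inputs$rr <- rr
  }

  # prevalence observations: beta around the point estimate
  if (is.finite(dists$prevalence_n_eff)) {
    p <- inputs$prevalence$prevalence
    n <- dists$prevalence_n_eff
    inputs$prevalence$prevalence <- rbeta(length(p), p * n, (1 - p) * n)
  }

  # mortality slopes: normal around the central fit
  fit <- dists$central_fit
  sd <- rep(dists$mortality_slope_sd %||% fit$slope_se, length.out = nrow(fit))
  sd[is.na(sd)] <- 0
  if (any(sd > 0)) {
    perturbed <- as_tibble(fit)
    drawn <- rnorm(nrow(fit), fit$slope, sd)
    perturbed$slope <- ifelse(sd > 0, drawn, fit$slope)
    attributes(perturbed)[c("reference_year", "window")] <-
      attributes(fit)[c("reference_year", "window")]
    class(perturbed) <- class(fit)
    fit <- perturbed
  }

  list(inputs = inputs, mortality_fit = fit)
}

draw_transition_table <- function(tt, n_eff, dirichlet_rows) {
  tt <- as_tibble(tt)
  keys <- intersect(c("year", "sex", "age", "from_state"), names(tt))
  if (dirichlet_rows) {
    g <- stats::rgamma(nrow(tt), shape = tt$probability * n_eff)
    g[tt$probability == 0] <- 0
    tt %>%
      mutate(.g = g) %>%
      group_by(across(all_of(keys))) %>%
      mutate(probability = .data$.g / sum(.data$.g)) %>%
      ungroup() %>%
      select(-".g")
  } else {
    stay <- tt$from_state == tt$to_state
    p <- tt$probability
    draw <- p
    idx <- !stay & p > 0 & p < 1
    draw[idx] <- rbeta(sum(idx), p[idx] * n_eff, (1 - p[idx]) * n_eff)
    out <- tt %>%
      mutate(probability = draw) %>%
      group_by(across(all_of(keys))) %>%
      mutate(probability = if_else(
        .data$from_state == .data$to_state,
        1 - sum(.data$probability[.data$from_state != .data$to_state]),
        .data$probability)) %>%
      ungroup()
    if (any(out$probability < 0)) {
      abort("a drawn transition row exceeds probability 1 (negative stay probability)",
            class = "bamsim_draw_error")
    }
    out
  }
}

#' Run the probabilistic sensitivity analysis
#'
#' Runs the scenario comparison once at the central parameters and
#' `n_iterations` times on sampled inputs, and summarises every reported
#' output cell with percentile 95% uncertainty bounds. Reproducible given
#' `seed`. A failed draw (e.g. one rejected for an invalid row) is logged
#' and skipped; more than 1% failures aborts.
#'
#' @param inputs Input bundle (see [run_comparison()]).
#' @param n_iterations Number of Monte Carlo iterations (1000 in production
#'   use; smaller values are fine for exploration).
#' @param seed Integer seed.
#' @param dists A [psa_distributions()] object (default: constructed from
#'   `inputs` with default hyperparameters).
#' @param keep_draws Keep the full cells-by-iterations draw matrix on the
#'   result (`$draws`); useful for diagnostics such as comparing paired and
#'   unpaired scenario-difference variances.
#' @param ... Passed on to [run_comparison()].
#' @return An `uncertainty_result`: tibble `cells` with columns `table`,
#'   `scenario`, `year`, `sex`, `measure`, `point`, `lower95`, `upper95`,
#'   plus fields `n_iterations`, `n_failed`, `seed`. The percentile bounds
#'   of a nonlinear model are not forced to bracket the central run.
#' @export
run_psa <- function(inputs, n_iterations = 1000, seed = 1,
                    dists = psa_distributions(inputs), keep_draws = FALSE, ...) {
  stopifnot(n_iterations >= 1)
  point <- run_comparison(inputs, mortality_fit = dists$central_fit, ...)
  cells <- comparison_cells(point)

  set.seed(seed)
  draws <- matrix(NA_real_, nrow = nrow(cells), ncol = n_iterations)
  failures <- character()
  for (k in seq_len(n_iterations)) {
    d <- sample_draw(dists)
    res <- tryCatch(
      run_comparison(d$inputs, mortality_fit = d$mortality_fit, ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("iteration %d: %s", k, conditionMessage(res)))
      next
    }
    v <- comparison_cells(res)
    if (!identical(v[c("table", "scenario", "year", "sex", "measure")],
                   cells[c("table", "scenario", "year", "sex", "measure")])) {
      failures <- c(failures, sprintf("iteration %d: cell layout mismatch", k))
      next
    }
    draws[, k] <- v$value
  }
  if (length(failures) > 0.01 * n_iterations) {
    abort(sprintf("PSA aborted: %d of %d iterations failed (> 1%%); first failure: %s",
                  length(failures), n_iterations, failures[1]))
  }
  ok <- colSums(is.na(draws)) == 0
  qs <- t(apply(draws[, ok, drop = FALSE], 1, quantile, probs = c(0.025, 0.975),
                names = FALSE))
  structure(
    list(
      cells = cells %>%
        rename(point = "value") %>%
        mutate(lower95 = qs[, 1], upper95 = qs[, 2]),
      n_iterations = n_iterations,
      n_used = sum(ok),
      n_failed = length(failures),
      failures = failures,
      seed = seed,
      draws = if (keep_draws) draws
    ),
    class = "uncertainty_result"
  )
}

#' @export
print.uncertainty_result <- function(x, ...) {
  cat(sprintf("<uncertainty_result> %d iterations (%d used, %d failed), seed %s\n",
              x$n_iterations, x$n_used, x$n_failed, format(x$seed)))
  print(head(x$cells, 10), ...)
  invisible(x)
}

#' @export
tidy.uncertainty_result <- function(x, ...) x$cells

#' @export
glance.uncertainty_result <- function(x, ...) {
  tibble(n_iterations = x$n_iterations, n_used = x$n_used,
         n_failed = x$n_failed, seed = x$seed, n_cells = nrow(x$cells))
}
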