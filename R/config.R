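#' Declarative run configuration
#'
#' One YAML document describes a whole comparison run: where the inputs come
#' from (a directory of CSVs, or parameters for the synthetic generator),
#' which scenarios to run, the mortality window and trend multiplier, the
#' probabilistic-sensitivity settings, the output directory, and the
#' design-option toggles (optimistic-path interpolation, healthy-state
#' definition, Dirichlet row sampling).
#'
#' ```yaml
#' inputs:
#'   synthetic:          # or `dir: path/to/csvs`
#'     seed: 42
#' scenarios: [baseline, constant, optimistic]
#' years: [2006, 2060]
#' since: 2015
#' mortality:
#'   window: [2007, 2016]
#'   slope_multiplier: 1
#' options:
#'   interpolation: loglinear
#' psa:
#'   iterations: 0       # 0 disables
#'   seed: 1
#' output_dir: out
#' ```
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    yaml::read_yaml(path)
  } else {
    path
  }
  if (is.null(cfg$inputs)) abort("config needs an 'inputs' section ('dir' or 'synthetic')")
  if (!is.null(cfg$inputs$dir) && !dir.exists(cfg$inputs$dir)) {
    abort(sprintf("config inputs$dir does not exist: %s", cfg$inputs$dir))
  }
  cfg$scenarios <- cfg$scenarios %||% c("baseline", "constant", "optimistic")
  if (length(cfg$scenarios) == 0) abort("scenario list must be non-empty")
  unknown <- setdiff(cfg$scenarios, c("baseline", "constant", "optimistic"))
  if (length(unknown) > 0) {
    abort(sprintf("unknown scenario label%s: %s",
                  if (length(unknown) > 1) "s" else "", paste(unknown, collapse = ", ")))
  }
  cfg$years <- as.integer(cfg$years %||% c(2006, 2060))
  cfg$since <- cfg$since %||% 2015
  cfg$mortality <- cfg$mortality %||% list()
  cfg$options <- cfg$options %||% list()
  cfg$psa <- cfg$psa %||% list(iterations = 0)
  structure(cfg, class = "run_config")
}

#' Execute a configured comparison run
#'
#' Loads or generates the inputs, runs [run_comparison()] (and [run_psa()]
#' when `psa$iterations > 0`), and writes every output table plus the run
#' summary to `output_dir`. Any stage error aborts naming the stage.
#'
#' @param config A file path or list accepted by [read_run_config()].
#' @param output_dir Overrides the config's `output_dir`.
#' @return The `scenario_comparison`, invisibly (with the
#'   `uncertainty_result` attached as `$psa` when run).
#' @export
run_from_config <- function(config, output_dir = NULL) {
  cfg <- read_run_config(config)
  inputs <- if (!is.null(cfg$inputs$dir)) {
    read_input_bundle(cfg$inputs$dir)
  } else if (!is.null(cfg$inputs$synthetic)) {
    generate_all(do.call(synthetic_config, cfg$inputs$synthetic))
  } else {
    abort("config inputs must name either 'dir' or 'synthetic'")
  }
  args <- list(
    inputs = inputs,
    scenarios = cfg$scenarios,
    years = cfg$years,
    since = cfg$since,
    mortality_window = if (!is.null(cfg$mortality$window)) as.integer(cfg$mortality$window),
    slope_multiplier = cfg$mortality$slope_multiplier %||% 1,
    mortality_base_year = cfg$mortality$base_year
  )
  opt_names <- intersect(names(cfg$options),
                         c("interpolation", "healthy_states", "target_year",
                           "reduction_fraction", "prevalence_floor", "min_age",
                           "report_years"))
  args <- c(args, cfg$options[opt_names])
  res <- do.call(run_comparison, args[!vapply(args, is.null, logical(1))])

  iterations <- cfg$psa$iterations %||% 0
  if (iterations > 0) {
    dists <- psa_distributions(
      inputs,
      tp_n_eff = cfg$psa$tp_n_eff %||% 1e4,
      prevalence_n_eff = cfg$psa$prevalence_n_eff %||% 1e4,
      rr_se = cfg$psa$rr_se,
      mortality_slope_sd = cfg$psa$mortality_slope_sd,
      mortality_window = args$mortality_window,
      dirichlet_rows = isTRUE(cfg$psa$dirichlet_rows)
    )
    psa_args <- args[setdiff(names(args), c("inputs"))]
    res$psa <- do.call(run_psa, c(
      list(inputs = inputs, n_iterations = iterations,
           seed = cfg$psa$seed %||% 1, dists = dists),
      psa_args[!vapply(psa_args, is.null, logical(1))]))
  }

  out_dir <- output_dir %||% cfg$output_dir
  if (!is.null(out_dir)) {
    write_comparison(res, out_dir)
    if (!is.null(res$psa)) {
      write_bamsim_csv(res$psa$cells, file.path(out_dir, "uncertainty.csv"))
    }
  }
  invisible(res)
}
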