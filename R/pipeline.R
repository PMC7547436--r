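#' Simulate a registry and write it to disk
#'
#' Pipeline stage wrapping [generate_registry()] with file output and a log
#' of the resolved configuration. Nothing is written if validation fails.
#'
#' @param config A [registry_config()].
#' @param out_csv Output CSV path.
#' @param quiet Suppress the configuration log.
#' @return The registry data frame, invisibly.
#' @export
pipeline_simulate_registry <- function(config, out_csv, quiet = FALSE) {
  stopifnot(inherits(config, "registry_config"))
  if (!quiet)
    message(sprintf("simulate-registry: n_patients=%d seed=%d censor_horizon=%g -> %s",
                    config$n_patients, config$seed, config$censor_horizon, out_csv))
  records <- generate_registry(config)
  write_registry(records, out_csv)
  invisible(records)
}

#' Run the base-case analysis and write the league table
#'
#' Evaluates every scenario in a parameter file through the cohort model
#' and writes the league table (total cost in millions, total QALYs, cost
#' per QALY, ICER or dominance label versus current practice) as CSV.
#'
#' @param out_csv Output CSV path.
#' @param params_file YAML parameter file; defaults to the one shipped
#'   with the package.
#' @param config A [model_config()].
#' @param comparator Usual-care arm name; must be present in the file.
#' @param quiet Suppress the configuration log.
#' @return The [league_table()], invisibly.
#' @export
pipeline_base_case <- function(out_csv, params_file = default_parameter_file(),
                               config = model_config(), comparator = "current",
                               quiet = FALSE) {
  scenarios <- read_scenario_params(params_file)
  if (!comparator %in% names(scenarios))
    stop("missing comparator scenario '", comparator, "' in ", params_file)
  if (!quiet)
    message(sprintf(
      "base-case: params=%s cohort=%g horizon=%d discount=%g age=%g -> %s",
      params_file, config$cohort_size, config$horizon, config$discount_rate,
      config$age, out_csv))
  results <- lapply(scenarios, run_scenario, config = config)
  tab <- league_table(results, comparator = comparator)
  utils::write.csv(tab, out_csv, row.names = FALSE, na = "")
  invisible(tab)
}

#' Run the probabilistic sensitivity analysis and write its outputs
#'
#' Runs [run_psa()] once and writes the per-iteration CSV plus one summary
#' CSV block per willingness-to-pay threshold (the per-iteration cost and
#' QALY draws are threshold-independent, so all summaries come from the
#' same run).
#'
#' @param out_iterations,out_summary Output CSV paths.
#' @param params_file YAML parameter file.
#' @param config A [model_config()].
#' @param n_iterations Monte-Carlo iterations.
#' @param seed RNG seed.
#' @param wtp Vector of willingness-to-pay thresholds (AUD/QALY); the
#'   first is the run's primary threshold.
#' @param rule Decision rule for the probability of error (see
#'   [probability_of_error()]).
#' @param quiet Suppress the configuration log.
#' @return Named list of [summarize_psa()] data frames, one per threshold,
#'   invisibly.
#' @export
pipeline_psa <- function(out_iterations, out_summary,
                         params_file = default_parameter_file(),
                         config = model_config(), n_iterations = 20000,
                         seed = 1L, wtp = c(28000, 42000, 67000),
                         rule = "pairwise", quiet = FALSE) {
  scenarios <- read_scenario_params(params_file)
  if (!quiet)
    message(sprintf(
      "psa: params=%s n_iterations=%d seed=%d wtp=%s rule=%s -> %s, %s",
      params_file, n_iterations, seed, paste(wtp, collapse = "/"), rule,
      out_iterations, out_summary))
  run <- run_psa(scenarios, config, n_iterations = n_iterations, seed = seed,
                 wtp = wtp[1L])
  write_psa_iterations(run, out_iterations)
  summaries <- lapply(wtp, function(w) summarize_psa(run, wtp = w, rule = rule))
  names(summaries) <- as.character(wtp)
  out <- do.call(rbind, lapply(wtp, function(w)
    cbind(wtp = w, summarize_psa(run, wtp = w, rule = rule))))
  utils::write.csv(out, out_summary, row.names = FALSE)
  invisible(summaries)
}
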