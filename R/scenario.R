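#' Weibull proportional-hazards transition parameters
#'
#' Bundles the rate, shape and age-coefficient triple defining one
#' time-dependent annual transition, together with the standard errors used
#' by the probabilistic sensitivity analysis. Under this parameterization the
#' hazard is `h(t) = lam * gamma * t^(gamma - 1) * exp(beta_age * age)`, i.e.
#' the age covariate acts multiplicatively on the rate parameter.
#'
#' @param lam Rate parameter (> 0, per year^gamma).
#' @param gamma Shape parameter (> 0). Values below 1 give a hazard that
#'   falls with time since state entry; above 1, a rising hazard.
#' @param beta_age Log-hazard-ratio per year of age.
#' @param sem_lam,sem_gamma,sem_beta Standard errors (>= 0); zero means the
#'   parameter is treated as known in the PSA.
#' @return An object of class `weibull_ph_params`.
#' @seealso [annual_transition_probability()], [fit_weibull_ph()]
#' @export
weibull_ph_params <- function(lam, gamma, beta_age,
                              sem_lam = 0, sem_gamma = 0, sem_beta = 0) {
  stopifnot(is.numeric(lam), is.numeric(gamma), is.numeric(beta_age))
  if (lam < 0) stop("'lam' must be non-negative")
  if (gamma <= 0) stop("'gamma' must be positive")
  if (sem_lam < 0 || sem_gamma < 0 || sem_beta < 0)
    stop("standard errors must be non-negative")
  structure(
    list(lam = lam, gamma = gamma, beta_age = beta_age,
         sem_lam = sem_lam, sem_gamma = sem_gamma, sem_beta = sem_beta),
    class = "weibull_ph_params"
  )
}

#' @export
print.weibull_ph_params <- function(x, ...) {
  cat(sprintf(
    "Weibull PH transition: lam = %.4g (SE %.2g), gamma = %.4g (SE %.2g), beta_age = %.4g (SE %.2g)\n",
    x$lam, x$sem_lam, x$gamma, x$sem_gamma, x$beta_age, x$sem_beta))
  invisible(x)
}

#' Fixed annual transition probability
#'
#' A transition probability that does not depend on time in state; its
#' standard error is used only when sampling Beta draws in the PSA.
#'
#' @param p Annual probability in `[0, 1]`.
#' @param sem Standard error (>= 0).
#' @return An object of class `fixed_annual_probability`.
#' @export
fixed_annual_probability <- function(p, sem = 0) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  if (sem < 0) stop("'sem' must be non-negative")
  structure(list(p = p, sem = sem), class = "fixed_annual_probability")
}

#' @export
print.fixed_annual_probability <- function(x, ...) {
  cat(sprintf("Fixed annual probability: %.4g (SE %.2g)\n", x$p, x$sem))
  invisible(x)
}

#' Allocation scenario
#'
#' One allocation option's complete parameter set: the three Weibull
#' transition triples (waitlist to transplant, transplant to graft failure,
#' transplant to death), the two fixed annual mortality probabilities shared
#' across options, state costs in 2018 AUD, and state utility weights.
#'
#' @param name Option identifier, e.g. `"current"` or `"option2"`.
#' @param p_transplant,p_graft_failure,p_death_post_tx
#'   [weibull_ph_params()] objects for the three time-dependent transitions.
#' @param p_death_waitlist,p_death_post_gf [fixed_annual_probability()]
#'   objects for waitlist mortality and mortality on dialysis after graft
#'   failure.
#' @param cost_tx_year1 Transplant episode cost incurred in the first
#'   post-transplant year (AUD).
#' @param cost_tx_subsequent Annual maintenance cost with a functioning
#'   graft (AUD/year).
#' @param cost_dialysis Annual dialysis cost (AUD/year), applied to both the
#'   waitlist and post-graft-failure states.
#' @param utility_transplant,utility_dialysis Quality-of-life weights in
#'   `[0, 1]` for the transplant and dialysis (waitlist or post-graft-failure)
#'   states.
#' @param cost_uncertainty Half-width, as a fraction of the point value, of
#'   the uniform cost distributions used in the PSA.
#' @param utility_transplant_ci,utility_dialysis_ci Length-2 bounds of the
#'   uniform utility distributions used in the PSA.
#' @return An object of class `allocation_scenario`.
#' @export
allocation_scenario <- function(name,
                                p_transplant, p_graft_failure, p_death_post_tx,
                                p_death_waitlist, p_death_post_gf,
                                cost_tx_year1, cost_tx_subsequent, cost_dialysis,
                                utility_transplant, utility_dialysis,
                                cost_uncertainty = 0.15,
                                utility_transplant_ci = c(utility_transplant, utility_transplant),
                                utility_dialysis_ci = c(utility_dialysis, utility_dialysis)) {
  stopifnot(inherits(p_transplant, "weibull_ph_params"),
            inherits(p_graft_failure, "weibull_ph_params"),
            inherits(p_death_post_tx, "weibull_ph_params"),
            inherits(p_death_waitlist, "fixed_annual_probability"),
            inherits(p_death_post_gf, "fixed_annual_probability"))
  if (cost_tx_year1 < 0 || cost_tx_subsequent < 0 || cost_dialysis < 0)
    stop("costs must be non-negative")
  if (utility_transplant < 0 || utility_transplant > 1 ||
      utility_dialysis < 0 || utility_dialysis > 1)
    stop("utilities must lie in [0, 1]")
  structure(
    list(name = as.character(name),
         p_transplant = p_transplant,
         p_graft_failure = p_graft_failure,
         p_death_post_tx = p_death_post_tx,
         p_death_waitlist = p_death_waitlist,
         p_death_post_gf = p_death_post_gf,
         cost_tx_year1 = cost_tx_year1,
         cost_tx_subsequent = cost_tx_subsequent,
         cost_dialysis = cost_dialysis,
         utility_transplant = utility_transplant,
         utility_dialysis = utility_dialysis,
         cost_uncertainty = cost_uncertainty,
         utility_transplant_ci = utility_transplant_ci,
         utility_dialysis_ci = utility_dialysis_ci),
    class = "allocation_scenario"
  )
}

#' @export
print.allocation_scenario <- function(x, ...) {
  cat(sprintf("Allocation scenario '%s'\n", x$name))
  cat(sprintf("  P1 transplant:     lam %.4g, gamma %.4g, beta_age %+.4g\n",
              x$p_transplant$lam, x$p_transplant$gamma, x$p_transplant$beta_age))
  cat(sprintf("  P2 graft failure:  lam %.4g, gamma %.4g, beta_age %+.4g\n",
              x$p_graft_failure$lam, x$p_graft_failure$gamma, x$p_graft_failure$beta_age))
  cat(sprintf("  P3 death post-tx:  lam %.4g, gamma %.4g, beta_age %+.4g\n",
              x$p_death_post_tx$lam, x$p_death_post_tx$gamma, x$p_death_post_tx$beta_age))
  cat(sprintf("  P4 waitlist death: %.4g   P5 post-graft-failure death: %.4g\n",
              x$p_death_waitlist$p, x$p_death_post_gf$p))
  cat(sprintf("  costs (AUD): tx y1 %.2f, tx later %.2f/y, dialysis %.2f/y\n",
              x$cost_tx_year1, x$cost_tx_subsequent, x$cost_dialysis))
  cat(sprintf("  utilities: transplant %.2f, dialysis %.2f\n",
              x$utility_transplant, x$utility_dialysis))
  invisible(x)
}

scenario_from_list <- function(name, opt, shared) {
  wb <- function(b) weibull_ph_params(b$lam, b$gamma, b$beta_age,
                                      b$sem_lam, b$sem_gamma, b$sem_beta)
  allocation_scenario(
    name = name,
    p_transplant = wb(opt$transplant),
    p_graft_failure = wb(opt$graft_failure),
    p_death_post_tx = wb(opt$death_post_tx),
    p_death_waitlist = fixed_annual_probability(shared$death_waitlist$p,
                                                shared$death_waitlist$sem),
    p_death_post_gf = fixed_annual_probability(shared$death_post_gf$p,
                                               shared$death_post_gf$sem),
    cost_tx_year1 = shared$cost_aud_2018$tx_year1$value,
    cost_tx_subsequent = shared$cost_aud_2018$tx_subsequent$value,
    cost_dialysis = shared$cost_aud_2018$dialysis$value,
    utility_transplant = shared$utility$transplant$value,
    utility_dialysis = shared$utility$dialysis$value,
    cost_uncertainty = shared$cost_aud_2018$tx_year1$uncertainty_fraction,
    utility_transplant_ci = c(shared$utility$transplant$ci_low,
                              shared$utility$transplant$ci_high),
    utility_dialysis_ci = c(shared$utility$dialysis$ci_low,
                            shared$utility$dialysis$ci_high)
  )
}

#' Read allocation scenarios from a YAML parameter file
#'
#' The file holds one `options:` block with the per-option Weibull triples
#' (keyed `transplant`, `graft_failure`, `death_post_tx`) and one `shared:`
#' block with the fixed probabilities, costs and utilities common to all
#' options. See the file returned by [default_parameter_file()] for the
#' layout.
#'
#' @param path Path to a YAML file.
#' @return A named list of [allocation_scenario()] objects.
#' @export
read_scenario_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$options) || is.null(raw$shared))
    stop("parameter file must contain 'options' and 'shared' blocks")
  out <- lapply(names(raw$options), function(nm)
    scenario_from_list(nm, raw$options[[nm]], raw$shared))
  names(out) <- names(raw$options)
  out
}

#' Write allocation scenarios to a YAML parameter file
#'
#' Inverse of [read_scenario_params()]; the shared block is taken from the
#' first scenario.
#'
#' @param scenarios Named list of [allocation_scenario()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_params <- function(scenarios, path) {
  stopifnot(length(scenarios) >= 1L)
  s1 <- scenarios[[1L]]
  wb <- function(p) list(lam = p$lam, gamma = p$gamma, beta_age = p$beta_age,
                         sem_lam = p$sem_lam, sem_gamma = p$sem_gamma,
                         sem_beta = p$sem_beta)
  opts <- lapply(scenarios, function(s)
    list(transplant = wb(s$p_transplant),
         graft_failure = wb(s$p_graft_failure),
         death_post_tx = wb(s$p_death_post_tx)))
  names(opts) <- vapply(scenarios, `[[`, "", "name")
  shared <- list(
    death_waitlist = list(p = s1$p_death_waitlist$p, sem = s1$p_death_waitlist$sem),
    death_post_gf = list(p = s1$p_death_post_gf$p, sem = s1$p_death_post_gf$sem),
    cost_aud_2018 = list(
      tx_year1 = list(value = s1$cost_tx_year1, uncertainty_fraction = s1$cost_uncertainty),
      tx_subsequent = list(value = s1$cost_tx_subsequent, uncertainty_fraction = s1$cost_uncertainty),
      dialysis = list(value = s1$cost_dialysis, uncertainty_fraction = s1$cost_uncertainty)),
    utility = list(
      transplant = list(value = s1$utility_transplant,
                        ci_low = s1$utility_transplant_ci[1L],
                        ci_high = s1$utility_transplant_ci[2L]),
      dialysis = list(value = s1$utility_dialysis,
                      ci_low = s1$utility_dialysis_ci[1L],
                      ci_high = s1$utility_dialysis_ci[2L])))
  yaml::write_yaml(list(options = opts, shared = shared), path)
  invisible(path)
}

#' Path to the default parameter file shipped with the package
#'
#' @return Path to the installed `scenario-parameters.yaml`.
#' @export
default_parameter_file <- function() {
  system.file("extdata", "scenario-parameters.yaml", package = "kidneyalloc",
              mustWork = TRUE)
}

#' Default allocation scenarios
#'
#' The five allocation options of the base-case analysis — current practice
#' plus the four longevity-matching options — loaded from the parameter file
#' shipped with the package.
#'
#' @return Named list of five [allocation_scenario()] objects:
#'   `current`, `option1`, `option2`, `option3`, `option4`.
#' @export
default_scenarios <- function() {
  read_scenario_params(default_parameter_file())
}
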