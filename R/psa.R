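#' Parameter distributions used in the probabilistic sensitivity analysis
#'
#' Tabulates, for one scenario, the distribution attached to every uncertain
#' parameter: Normal(mean, SEM) truncated at a small positive floor for the
#' Weibull rate and shape parameters, Normal for the age coefficients, Beta
#' (shape parameters solved by method of moments from mean and SEM) for the
#' fixed annual probabilities, and Uniform for costs (point value +/- the
#' configured fraction) and utilities (over their interval bounds).
#' Parameters with zero SEM or zero-width ranges are degenerate and return
#' their point value.
#'
#' @param scenario An [allocation_scenario()].
#' @return A data frame with columns `parameter`, `family`, `arg1`, `arg2`
#'   (mean/SEM for Normal and Beta; bounds for Uniform).
#' @export
psa_distributions <- function(scenario) {
  stopifnot(inherits(scenario, "allocation_scenario"))
  wb <- function(prefix, p) data.frame(
    parameter = paste0(prefix, c("_lam", "_gamma", "_beta_age")),
    family = c("truncated normal", "truncated normal", "normal"),
    arg1 = c(p$lam, p$gamma, p$beta_age),
    arg2 = c(p$sem_lam, p$sem_gamma, p$sem_beta))
  u <- scenario$cost_uncertainty
  rbind(
    wb("transplant", scenario$p_transplant),
    wb("graft_failure", scenario$p_graft_failure),
    wb("death_post_tx", scenario$p_death_post_tx),
    data.frame(parameter = c("death_waitlist", "death_post_gf"),
               family = "beta",
               arg1 = c(scenario$p_death_waitlist$p, scenario$p_death_post_gf$p),
               arg2 = c(scenario$p_death_waitlist$sem, scenario$p_death_post_gf$sem)),
    data.frame(parameter = c("cost_tx_year1", "cost_tx_subsequent", "cost_dialysis"),
               family = "uniform",
               arg1 = c(scenario$cost_tx_year1, scenario$cost_tx_subsequent,
                        scenario$cost_dialysis) * (1 - u),
               arg2 = c(scenario$cost_tx_year1, scenario$cost_tx_subsequent,
                        scenario$cost_dialysis) * (1 + u)),
    data.frame(parameter = c("utility_transplant", "utility_dialysis"),
               family = "uniform",
               arg1 = c(scenario$utility_transplant_ci[1L], scenario$utility_dialysis_ci[1L]),
               arg2 = c(scenario$utility_transplant_ci[2L], scenario$utility_dialysis_ci[2L]))
  )
}

# Positive-truncated normal draws (floor at 1e-8 keeps the Weibull rate and
# shape valid; with the published SEMs truncation is vanishingly rare).
rnorm_pos <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 1e-8)

# Beta draws with shapes solved from (mean, sem) by method of moments;
# degenerate at sem = 0.
rbeta_mm <- function(n, mean, sem) {
  if (sem == 0) return(rep(mean, n))
  v <- sem^2
  if (v >= mean * (1 - mean))
    stop(sprintf("infeasible Beta moments: sem^2 = %.3g >= mean(1-mean) = %.3g",
                 v, mean * (1 - mean)))
  a <- mean * (mean * (1 - mean) / v - 1)
  stats::rbeta(n, a, a * (1 - mean) / mean)
}

runif_range <- function(n, lo, hi) {
  if (lo == hi) rep(lo, n) else stats::runif(n, lo, hi)
}

# Draw the option-specific Weibull parameter vectors for n iterations, in a
# fixed parameter order so results do not depend on iteration order.
sample_weibull_block <- function(s, n) {
  list(l1 = rnorm_pos(n, s$p_transplant$lam, s$p_transplant$sem_lam),
       g1 = rnorm_pos(n, s$p_transplant$gamma, s$p_transplant$sem_gamma),
       b1 = stats::rnorm(n, s$p_transplant$beta_age, s$p_transplant$sem_beta),
       l2 = rnorm_pos(n, s$p_graft_failure$lam, s$p_graft_failure$sem_lam),
       g2 = rnorm_pos(n, s$p_graft_failure$gamma, s$p_graft_failure$sem_gamma),
       b2 = stats::rnorm(n, s$p_graft_failure$beta_age, s$p_graft_failure$sem_beta),
       l3 = rnorm_pos(n, s$p_death_post_tx$lam, s$p_death_post_tx$sem_lam),
       g3 = rnorm_pos(n, s$p_death_post_tx$gamma, s$p_death_post_tx$sem_gamma),
       b3 = stats::rnorm(n, s$p_death_post_tx$beta_age, s$p_death_post_tx$sem_beta))
}

# Draw the parameters shared across options (fixed probabilities, costs,
# utilities): one value per iteration, common to every option so that
# within-iteration comparisons differ only through the option-specific
# transition parameters.
sample_shared_block <- function(s, n) {
  u <- s$cost_uncertainty
  list(p4 = rbeta_mm(n, s$p_death_waitlist$p, s$p_death_waitlist$sem),
       p5 = rbeta_mm(n, s$p_death_post_gf$p, s$p_death_post_gf$sem),
       c_tx1 = runif_range(n, s$cost_tx_year1 * (1 - u), s$cost_tx_year1 * (1 + u)),
       c_tx2 = runif_range(n, s$cost_tx_subsequent * (1 - u), s$cost_tx_subsequent * (1 + u)),
       c_dial = runif_range(n, s$cost_dialysis * (1 - u), s$cost_dialysis * (1 + u)),
       u_tx = runif_range(n, s$utility_transplant_ci[1L], s$utility_transplant_ci[2L]),
       u_dial = runif_range(n, s$utility_dialysis_ci[1L], s$utility_dialysis_ci[2L]))
}

#' Sample one scenario from its parameter distributions
#'
#' Draws a single random realization of every uncertain parameter of a
#' scenario from the distributions listed by [psa_distributions()], using
#' the current RNG state. With all SEMs zero and zero-width ranges the base
#' scenario is returned exactly.
#'
#' @param base An [allocation_scenario()].
#' @return An [allocation_scenario()] with sampled point values (sampled
#'   scenarios carry zero SEMs).
#' @export
sample_scenario <- function(base) {
  stopifnot(inherits(base, "allocation_scenario"))
  w <- sample_weibull_block(base, 1L)
  s <- sample_shared_block(base, 1L)
  allocation_scenario(
    name = base$name,
    p_transplant = weibull_ph_params(w$l1, w$g1, w$b1),
    p_graft_failure = weibull_ph_params(w$l2, w$g2, w$b2),
    p_death_post_tx = weibull_ph_params(w$l3, w$g3, w$b3),
    p_death_waitlist = fixed_annual_probability(s$p4),
    p_death_post_gf = fixed_annual_probability(s$p5),
    cost_tx_year1 = s$c_tx1, cost_tx_subsequent = s$c_tx2,
    cost_dialysis = s$c_dial,
    utility_transplant = s$u_tx, utility_dialysis = s$u_dial,
    cost_uncertainty = 0)
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: per iteration, every
#' scenario (including current practice) is re-evaluated through the full
#' cohort model under parameters drawn from its [psa_distributions()].
#' Parameters shared across options — the fixed mortality probabilities,
#' costs and utilities — are drawn once per iteration and used by all arms,
#' so within-iteration increments reflect only the allocation-specific
#' transition parameters plus the shared uncertainty. Draws are taken
#' parameter by parameter in a fixed documented order, making the run
#' reproducible for a given seed and invariant to iteration order.
#'
#' @param scenarios Named list of [allocation_scenario()] objects; must
#'   include the comparator arm.
#' @param config A [model_config()].
#' @param n_iterations Number of Monte-Carlo iterations.
#' @param seed Integer seed for the RNG.
#' @param wtp Willingness-to-pay threshold (AUD/QALY) attached to the run
#'   as its default for NMB summaries.
#' @param comparator Name of the usual-care arm.
#' @return An object of class `psa_run`: per-iteration total cost and QALY
#'   matrices (iterations x options), plus the run settings.
#' @export
run_psa <- function(scenarios, config = model_config(), n_iterations = 20000,
                    seed = 1L, wtp = 28000, comparator = "current") {
  stopifnot(length(scenarios) >= 1L, n_iterations >= 1L)
  if (!comparator %in% names(scenarios))
    stop("comparator scenario '", comparator, "' not found")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- as.integer(n_iterations)
  shared <- sample_shared_block(scenarios[[comparator]], n)
  K <- length(scenarios)
  cost <- qaly <- matrix(NA_real_, n, K, dimnames = list(NULL, names(scenarios)))
  for (nm in names(scenarios)) {
    par <- c(sample_weibull_block(scenarios[[nm]], n), shared)
    agg <- cohort_engine(par, config)
    out <- accumulate_engine(agg, par, config)
    cost[, nm] <- out$cost
    qaly[, nm] <- out$qaly
  }
  structure(list(cost = cost, qaly = qaly, wtp = wtp, seed = seed,
                 n_iterations = n, comparator = comparator, config = config),
            class = "psa_run")
}

#' @export
print.psa_run <- function(x, ...) {
  cat(sprintf("PSA run: %d iterations, %d options (%s), WTP %s AUD/QALY, seed %d\n",
              x$n_iterations, ncol(x$cost),
              paste(colnames(x$cost), collapse = ", "),
              format(x$wtp, big.mark = ","), x$seed))
  invisible(x)
}

psa_nmb <- function(run, wtp = run$wtp) wtp * run$qaly - run$cost

#' Probability of error of an allocation decision
#'
#' Fraction of PSA iterations in which the option does *not* return the
#' highest net monetary benefit, i.e. one minus the probability that
#' choosing the option is the correct decision. Under the default
#' `"pairwise"` rule the option is compared with current practice alone;
#' under `"all"` it must strictly exceed every other option and current
#' practice. Ties count as non-highest in both rules.
#'
#' @param run A [run_psa()] result.
#' @param option Option name.
#' @param wtp Willingness-to-pay threshold; defaults to the run's.
#' @param rule `"pairwise"` (versus current practice only) or `"all"`
#'   (versus the full comparator set).
#' @return A fraction in `[0, 1]`.
#' @export
probability_of_error <- function(run, option, wtp = run$wtp,
                                 rule = c("pairwise", "all")) {
  stopifnot(inherits(run, "psa_run"))
  rule <- match.arg(rule)
  if (!option %in% colnames(run$cost)) stop("unknown option: ", option)
  nmb <- psa_nmb(run, wtp)
  if (rule == "pairwise") {
    1 - mean(nmb[, option] > nmb[, run$comparator])
  } else {
    others <- nmb[, setdiff(colnames(nmb), option), drop = FALSE]
    1 - mean(nmb[, option] > apply(others, 1L, max))
  }
}

#' Summarize a PSA run
#'
#' Per option (current practice excluded), the mean and min-max range over
#' iterations of the incremental cost, incremental QALYs and incremental
#' net monetary benefit versus current practice, plus the probability of
#' error under the chosen decision rule.
#'
#' @inheritParams probability_of_error
#' @return A data frame of class `psa_summary`, one row per option.
#' @export
summarize_psa <- function(run, wtp = run$wtp, rule = c("pairwise", "all")) {
  stopifnot(inherits(run, "psa_run"))
  rule <- match.arg(rule)
  opts <- setdiff(colnames(run$cost), run$comparator)
  nmb <- psa_nmb(run, wtp)
  rows <- lapply(opts, function(o) {
    dc <- run$cost[, o] - run$cost[, run$comparator]
    dq <- run$qaly[, o] - run$qaly[, run$comparator]
    dn <- nmb[, o] - nmb[, run$comparator]
    data.frame(option = o,
               mean_inc_cost = mean(dc), min_inc_cost = min(dc), max_inc_cost = max(dc),
               mean_inc_qaly = mean(dq), min_inc_qaly = min(dq), max_inc_qaly = max(dq),
               mean_inc_nmb = mean(dn), min_inc_nmb = min(dn), max_inc_nmb = max(dn),
               probability_of_error = probability_of_error(run, o, wtp, rule),
               row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("psa_summary", "data.frame"),
            wtp = wtp, rule = rule, n_iterations = run$n_iterations)
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("PSA summary (%d iterations, WTP %s AUD/QALY, %s decision rule)\n",
              attr(x, "n_iterations"), format(attr(x, "wtp"), big.mark = ","),
              attr(x, "rule")))
  y <- data.frame(option = x$option,
                  `inc cost (M)` = sprintf("%.2f", x$mean_inc_cost / 1e6),
                  `inc QALY` = sprintf("%.0f", x$mean_inc_qaly),
                  `inc NMB (M)` = sprintf("%.2f", x$mean_inc_nmb / 1e6),
                  `P(error)` = sprintf("%.3f", x$probability_of_error),
                  check.names = FALSE)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Write per-iteration PSA results to CSV
#'
#' Long format: one row per (iteration, option) with cost, QALYs and NMB at
#' the run's threshold.
#'
#' @param run A [run_psa()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_iterations <- function(run, path) {
  stopifnot(inherits(run, "psa_run"))
  nmb <- psa_nmb(run)
  opts <- colnames(run$cost)
  out <- data.frame(
    iteration = rep(seq_len(run$n_iterations), times = length(opts)),
    option = rep(opts, each = run$n_iterations),
    cost = as.vector(run$cost), qaly = as.vector(run$qaly),
    nmb = as.vector(nmb))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
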