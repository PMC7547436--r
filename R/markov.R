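#' Markov model configuration
#'
#' Settings shared by every cohort evaluation: cohort size, horizon,
#' discounting, the fixed evaluation age, and the accounting flags for
#' conventions that published cost-effectiveness models frequently leave
#' unstated.
#'
#' @param cohort_size Number of patients starting on the waitlist.
#' @param horizon Number of one-year cycles.
#' @param discount_rate Annual discount rate applied to both costs and
#'   QALYs.
#' @param age Evaluation age in years; held fixed over the horizon (the
#'   cohort does not age within the model).
#' @param half_cycle_correction If `TRUE`, payoffs accrue on the average of
#'   the occupancies at the start and end of each cycle (trapezoid rule)
#'   instead of the end-of-cycle occupancy.
#' @param discount_from_first_cycle If `TRUE`, the first cycle's payoff is
#'   discounted by `(1 + discount_rate)^-1`; the default leaves the first
#'   cycle undiscounted (factor `(1 + discount_rate)^0`).
#' @param maintenance_in_first_year If `TRUE` (default), the annual graft
#'   maintenance cost accrues in every post-transplant year including the
#'   first, with the transplant episode cost added on top in year one; if
#'   `FALSE`, year one carries the episode cost only.
#' @return An object of class `model_config`.
#' @export
model_config <- function(cohort_size = 1000, horizon = 20,
                         discount_rate = 0.05, age = 50,
                         half_cycle_correction = FALSE,
                         discount_from_first_cycle = FALSE,
                         maintenance_in_first_year = TRUE) {
  if (horizon < 1 || horizon != floor(horizon)) stop("'horizon' must be a positive integer")
  if (cohort_size <= 0) stop("'cohort_size' must be positive")
  if (discount_rate < 0) stop("'discount_rate' must be non-negative")
  structure(list(cohort_size = cohort_size, horizon = as.integer(horizon),
                 discount_rate = discount_rate, age = age,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 discount_from_first_cycle = isTRUE(discount_from_first_cycle),
                 maintenance_in_first_year = isTRUE(maintenance_in_first_year)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "Model config: %g patients, %d one-year cycles, %.1f%% discount, age %g\n",
    x$cohort_size, x$horizon, 100 * x$discount_rate, x$age))
  cat(sprintf("  half-cycle correction: %s; first cycle discounted: %s; maintenance in year 1: %s\n",
              x$half_cycle_correction, x$discount_from_first_cycle,
              x$maintenance_in_first_year))
  invisible(x)
}

# Flatten a scenario into the numeric parameter list consumed by the engine.
# Each element may be a scalar or a length-m vector (one value per PSA draw).
scenario_engine_par <- function(s) {
  list(l1 = s$p_transplant$lam, g1 = s$p_transplant$gamma, b1 = s$p_transplant$beta_age,
       l2 = s$p_graft_failure$lam, g2 = s$p_graft_failure$gamma, b2 = s$p_graft_failure$beta_age,
       l3 = s$p_death_post_tx$lam, g3 = s$p_death_post_tx$gamma, b3 = s$p_death_post_tx$beta_age,
       p4 = s$p_death_waitlist$p, p5 = s$p_death_post_gf$p,
       c_tx1 = s$cost_tx_year1, c_tx2 = s$cost_tx_subsequent, c_dial = s$cost_dialysis,
       u_tx = s$utility_transplant, u_dial = s$utility_dialysis)
}

weibull_cycle_prob <- function(lam, gam, beta, age, t) {
  pmin(pmax(1 - exp(lam * exp(beta * age) * ((t - 1)^gam - t^gam)), 0), 1)
}

# Core cohort propagation, vectorized over m parameter draws.
#
# Dynamics per cycle: waitlist splits into new transplants (P1 at model time,
# the whole cohort having been listed at time zero), waitlist deaths (P4) and
# stayers; each transplant tunnel k (time since transplant) splits by P2/P3
# evaluated at k into graft failures, deaths and survivors who advance to
# tunnel k+1; the post-graft-failure dialysis state loses a fixed fraction P5
# to death. Competing exits are independently computed annual probabilities,
# proportionally rescaled (with a warning) in the rare case their sum
# exceeds 1. Death is absorbing.
#
# Returns per-cycle aggregate occupancies (rows = cycles 0..horizon):
# waitlist W, first-year tunnel T1, later tunnels Trest, post-graft-failure
# G, dead D, each an m x (horizon+1) matrix, plus the full per-tunnel trace
# when m == 1.
cohort_engine <- function(par, config) {
  H <- config$horizon
  age <- config$age
  m <- max(lengths(par))
  par <- lapply(par, rep_len, m)
  k <- seq_len(H)

  # m x H matrices of tunnel-time cycle probabilities
  PG <- vapply(k, function(t) weibull_cycle_prob(par$l2, par$g2, par$b2, age, t),
               numeric(m))
  PD <- vapply(k, function(t) weibull_cycle_prob(par$l3, par$g3, par$b3, age, t),
               numeric(m))
  if (is.null(dim(PG))) { PG <- matrix(PG, 1L, H); PD <- matrix(PD, 1L, H) }
  s23 <- PG + PD
  if (any(s23 > 1)) {
    warning("graft-failure and death probabilities exceed 1 in combination; rescaled proportionally")
    i <- s23 > 1
    PG[i] <- PG[i] / s23[i]
    PD[i] <- PD[i] / s23[i]
  }

  W <- rep(config$cohort_size, m)
  Tun <- matrix(0, m, H)
  G <- numeric(m)
  D <- numeric(m)

  aggW <- aggT1 <- aggTr <- aggG <- aggD <- matrix(0, m, H + 1L)
  aggW[, 1L] <- W
  trace_tunnels <- if (m == 1L) matrix(0, H + 1L, H) else NULL
  warned <- FALSE

  for (t in k) {
    ptx <- weibull_cycle_prob(par$l1, par$g1, par$b1, age, t)
    p4 <- par$p4
    s14 <- ptx + p4
    if (any(s14 > 1)) {
      if (!warned) {
        warning("transplant and waitlist-death probabilities exceed 1 in combination; rescaled proportionally")
        warned <- TRUE
      }
      i <- s14 > 1
      ptx[i] <- ptx[i] / s14[i]
      p4[i] <- p4[i] / s14[i]
    }
    new_tx <- W * ptx
    w_dead <- W * p4
    W <- W - new_tx - w_dead

    gf <- Tun * PG
    td <- Tun * PD
    surv <- Tun - gf - td
    Tun <- cbind(new_tx, surv[, -H, drop = FALSE], deparse.level = 0)

    g_dead <- G * par$p5
    G <- G - g_dead + rowSums(gf)
    D <- D + w_dead + rowSums(td) + g_dead

    aggW[, t + 1L] <- W
    aggT1[, t + 1L] <- Tun[, 1L]
    aggTr[, t + 1L] <- rowSums(Tun[, -1L, drop = FALSE])
    aggG[, t + 1L] <- G
    aggD[, t + 1L] <- D
    if (m == 1L) trace_tunnels[t + 1L, ] <- Tun[1L, ]
  }

  list(W = aggW, T1 = aggT1, Trest = aggTr, G = aggG, D = aggD,
       tunnels = trace_tunnels, m = m)
}

# Discount factors for payoff cycles 1..H.
discount_factors <- function(config) {
  off <- if (config$discount_from_first_cycle) 0 else 1
  (1 + config$discount_rate)^(-(seq_len(config$horizon) - off))
}

# Discounted totals from engine aggregates; vectorized over draws.
accumulate_engine <- function(agg, par, config) {
  H <- config$horizon
  m <- agg$m
  par <- lapply(par, rep_len, m)
  df <- discount_factors(config)
  idx1 <- seq_len(H)            # start-of-cycle occupancy rows
  idx2 <- idx1 + 1L             # end-of-cycle occupancy rows
  wgt2 <- if (config$half_cycle_correction) 0.5 else 1
  wgt1 <- 1 - wgt2
  occ <- function(Mx) wgt1 * Mx[, idx1, drop = FALSE] + wgt2 * Mx[, idx2, drop = FALSE]
  W <- occ(agg$W); T1 <- occ(agg$T1); Tr <- occ(agg$Trest); G <- occ(agg$G)
  c_t1 <- par$c_tx1 + if (config$maintenance_in_first_year) par$c_tx2 else 0
  cost <- (W + G) * par$c_dial + T1 * c_t1 + Tr * par$c_tx2
  qaly <- (W + G) * par$u_dial + (T1 + Tr) * par$u_tx
  # row-wise discounted sums (kept free of BLAS so results are identical
  # whether one draw or many is propagated)
  dfm <- matrix(df, nrow = m, ncol = H, byrow = TRUE)
  list(cost = rowSums(cost * dfm), qaly = rowSums(qaly * dfm))
}

#' Outgoing transition probabilities for one cycle
#'
#' The per-state outgoing probability rows of the transition structure at a
#' given model cycle and tunnel index: the waitlist row uses the transplant
#' hazard evaluated at model time (the whole cohort is listed at time zero)
#' plus the fixed waitlist mortality; the transplant-tunnel row uses the
#' graft-failure and post-transplant mortality hazards evaluated at
#' `tunnel_index` (time since transplant); the post-graft-failure row uses
#' the fixed dialysis mortality. Each row sums to 1 exactly; if the
#' competing exit probabilities of a row sum beyond 1 they are
#' proportionally rescaled with a warning.
#'
#' @param scenario An [allocation_scenario()].
#' @param config A [model_config()].
#' @param model_cycle Model cycle (1-based, <= horizon).
#' @param tunnel_index Years since transplant for the tunnel row
#'   (1 <= tunnel_index <= model_cycle).
#' @return A list of named probability vectors, one per transient state
#'   (`waitlist`, `tunnel`, `post_graft_failure`) plus the absorbing
#'   `death` row.
#' @export
cycle_transition_probabilities <- function(scenario, config, model_cycle,
                                           tunnel_index = 1L) {
  stopifnot(inherits(scenario, "allocation_scenario"),
            inherits(config, "model_config"))
  if (model_cycle < 1 || model_cycle > config$horizon)
    stop("'model_cycle' must lie in 1..horizon")
  if (tunnel_index < 1 || tunnel_index > model_cycle)
    stop("'tunnel_index' must lie in 1..model_cycle")
  age <- config$age
  ptx <- annual_transition_probability(scenario$p_transplant, age, model_cycle)
  p4 <- scenario$p_death_waitlist$p
  if (ptx + p4 > 1) {
    warning("waitlist exit probabilities exceed 1 in combination; rescaled proportionally")
    s <- ptx + p4
    ptx <- ptx / s
    p4 <- p4 / s
  }
  pgf <- annual_transition_probability(scenario$p_graft_failure, age, tunnel_index)
  pdt <- annual_transition_probability(scenario$p_death_post_tx, age, tunnel_index)
  if (pgf + pdt > 1) {
    warning("transplant exit probabilities exceed 1 in combination; rescaled proportionally")
    s <- pgf + pdt
    pgf <- pgf / s
    pdt <- pdt / s
  }
  p5 <- scenario$p_death_post_gf$p
  list(
    waitlist = c(transplant = ptx, death = p4, stay = 1 - ptx - p4),
    tunnel = c(graft_failure = pgf, death = pdt, stay = 1 - pgf - pdt),
    post_graft_failure = c(death = p5, stay = 1 - p5),
    death = c(death = 1)
  )
}

#' Run the cohort model for one allocation scenario
#'
#' Propagates the full cohort, which starts on the waitlist, cycle by cycle
#' through the four health states (waitlist, transplanted, post-graft-failure
#' dialysis, death). The transplant state is expanded into one tunnel state
#' per year since transplant so that the graft-failure and post-transplant
#' mortality hazards — fitted on the time-since-transplant scale — are
#' evaluated at the correct sojourn time. Graft failure moves patients
#' permanently to dialysis (no re-listing); death is absorbing.
#'
#' @param scenario An [allocation_scenario()].
#' @param config A [model_config()].
#' @return An object of class `cohort_trace`: a `(horizon + 1) x
#'   (horizon + 3)` occupancy matrix (rows cycle 0..horizon; columns
#'   `waitlist`, `tunnel_1..tunnel_horizon`, `post_graft_failure`, `dead`)
#'   with the scenario name and config attached as attributes. Occupancies
#'   sum to the cohort size in every row.
#' @examples
#' sc <- default_scenarios()
#' tr <- run_cohort(sc$current, model_config())
#' head(rowSums(tr))   # mass conservation
#' @export
run_cohort <- function(scenario, config = model_config()) {
  stopifnot(inherits(scenario, "allocation_scenario"),
            inherits(config, "model_config"))
  par <- scenario_engine_par(scenario)
  agg <- cohort_engine(par, config)
  H <- config$horizon
  trace <- cbind(agg$W[1L, ], agg$tunnels, agg$G[1L, ], agg$D[1L, ])
  dimnames(trace) <- list(cycle = 0:H,
                          state = c("waitlist", paste0("tunnel_", seq_len(H)),
                                    "post_graft_failure", "dead"))
  structure(trace, class = c("cohort_trace", "matrix"),
            scenario = scenario$name, config = config)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Cohort trace, scenario '%s': %g patients over %d cycles\n",
              attr(x, "scenario"), cfg$cohort_size, cfg$horizon))
  H <- cfg$horizon
  compact <- cbind(waitlist = x[, "waitlist"],
                   transplanted = rowSums(x[, 1L + seq_len(H), drop = FALSE]),
                   post_graft_failure = x[, "post_graft_failure"],
                   dead = x[, "dead"])
  print(round(compact, 1))
  invisible(x)
}

#' Total discounted cost and QALYs from a cohort trace
#'
#' Per cycle, the waitlist and post-graft-failure states accrue the annual
#' dialysis cost and the dialysis utility weight; first-year transplant
#' occupancy accrues the transplant episode cost (plus, by default, the
#' annual maintenance cost — see [model_config()]); later tunnel occupancy
#' accrues the maintenance cost and the transplant utility weight; death
#' accrues nothing. Payoffs are discounted per cycle and summed over the
#' horizon.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param scenario The [allocation_scenario()] supplying payoffs.
#' @param config The [model_config()] used to produce the trace.
#' @return An [economic_result()] with the cohort's total discounted cost
#'   (AUD) and QALYs.
#' @export
accumulate_outcomes <- function(trace, scenario, config = attr(trace, "config")) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(scenario, "allocation_scenario"))
  H <- config$horizon
  tot <- rowSums(trace)
  if (any(abs(tot - config$cohort_size) > 1e-6 * config$cohort_size))
    stop("trace does not conserve cohort mass")
  tun <- trace[, 1L + seq_len(H), drop = FALSE]
  agg <- list(W = matrix(trace[, "waitlist"], 1L),
              T1 = matrix(tun[, 1L], 1L),
              Trest = matrix(rowSums(tun[, -1L, drop = FALSE]), 1L),
              G = matrix(trace[, "post_graft_failure"], 1L),
              m = 1L)
  par <- scenario_engine_par(scenario)
  out <- accumulate_engine(agg, par, config)
  economic_result(out$cost, out$qaly, name = scenario$name)
}

#' Economic result for one model arm
#'
#' @param total_cost Total discounted cost for the whole cohort (AUD).
#' @param total_qaly Total discounted QALYs for the whole cohort.
#' @param name Optional arm label.
#' @return An object of class `economic_result`.
#' @export
economic_result <- function(total_cost, total_qaly, name = NULL) {
  if (total_cost < 0) stop("'total_cost' must be non-negative")
  structure(list(total_cost = total_cost, total_qaly = total_qaly, name = name),
            class = "economic_result")
}

#' @export
print.economic_result <- function(x, ...) {
  cat(sprintf("Economic result%s: %.1f M AUD, %.0f QALYs\n",
              if (is.null(x$name)) "" else paste0(" (", x$name, ")"),
              x$total_cost / 1e6, x$total_qaly))
  invisible(x)
}

#' Run one scenario end to end
#'
#' Convenience wrapper: [run_cohort()] followed by [accumulate_outcomes()].
#'
#' @inheritParams run_cohort
#' @return An [economic_result()].
#' @export
run_scenario <- function(scenario, config = model_config()) {
  accumulate_outcomes(run_cohort(scenario, config), scenario, config)
}
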