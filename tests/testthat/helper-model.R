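# Shared fixtures built in code.

# A scenario with hand-picked simple parameters, for closed-form checks.
toy_scenario <- function(name = "toy",
                         l1 = 0.2, g1 = 1, b1 = 0,
                         l2 = 0.1, g2 = 1, b2 = 0,
                         l3 = 0.05, g3 = 1, b3 = 0,
                         p4 = 0.02, p5 = 0.1,
                         c1 = 100000, c2 = 14000, cd = 80000,
                         ut = 0.82, ud = 0.70) {
  allocation_scenario(
    name = name,
    p_transplant = weibull_ph_params(l1, g1, b1),
    p_graft_failure = weibull_ph_params(l2, g2, b2),
    p_death_post_tx = weibull_ph_params(l3, g3, b3),
    p_death_waitlist = fixed_annual_probability(p4),
    p_death_post_gf = fixed_annual_probability(p5),
    cost_tx_year1 = c1, cost_tx_subsequent = c2, cost_dialysis = cd,
    utility_transplant = ut, utility_dialysis = ud)
}

# Individual-level Monte-Carlo simulation of the same transition process:
# each patient walks the chain independently, with graft-failure and
# post-transplant death probabilities indexed by personal time since
# transplant. Independent oracle for the cohort engine.
microsim_occupancy <- function(scenario, config, n, seed) {
  set.seed(seed)
  H <- config$horizon
  age <- config$age
  pgf <- annual_transition_probability(scenario$p_graft_failure, age, seq_len(H))
  pdt <- annual_transition_probability(scenario$p_death_post_tx, age, seq_len(H))
  s <- pgf + pdt
  resc <- s > 1
  pgf[resc] <- pgf[resc] / s[resc]
  pdt[resc] <- pdt[resc] / s[resc]
  p4 <- scenario$p_death_waitlist$p
  p5 <- scenario$p_death_post_gf$p

  state <- rep(1L, n)               # 1 waitlist, 2 transplanted, 3 post-gf, 4 dead
  tunnel <- integer(n)              # years since transplant while in state 2
  occ <- matrix(0, H + 1L, 4L,
                dimnames = list(cycle = 0:H,
                                state = c("waitlist", "transplanted",
                                          "post_graft_failure", "dead")))
  occ[1L, 1L] <- n
  for (t in seq_len(H)) {
    ptx <- annual_transition_probability(scenario$p_transplant, age, t)
    stx <- ptx + p4
    if (stx > 1) { ptx <- ptx / stx; p4t <- p4 / stx } else p4t <- p4

    u <- stats::runif(n)
    wl <- state == 1L
    tx <- state == 2L
    gf <- state == 3L

    to_tx <- wl & u < ptx
    to_dead_wl <- wl & u >= ptx & u < ptx + p4t
    pg <- pd <- numeric(n)
    pg[tx] <- pgf[tunnel[tx]]
    pd[tx] <- pdt[tunnel[tx]]
    to_gf <- tx & u < pg
    to_dead_tx <- tx & u >= pg & u < pg + pd
    to_dead_gf <- gf & u < p5

    tunnel[tx & !to_gf & !to_dead_tx] <- tunnel[tx & !to_gf & !to_dead_tx] + 1L
    state[to_tx] <- 2L
    tunnel[to_tx] <- 1L
    state[to_gf] <- 3L
    state[to_dead_wl | to_dead_tx | to_dead_gf] <- 4L

    occ[t + 1L, ] <- tabulate(state, nbins = 4L)
  }
  occ / n
}

# Collapse a cohort trace to the four aggregate states, as fractions.
trace_fractions <- function(trace, config) {
  H <- config$horizon
  cbind(waitlist = trace[, "waitlist"],
        transplanted = rowSums(trace[, 1L + seq_len(H), drop = FALSE]),
        post_graft_failure = trace[, "post_graft_failure"],
        dead = trace[, "dead"]) / config$cohort_size
}
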