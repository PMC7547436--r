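small_config <- function(n = 500, seed = 1, ...) {
  sc <- default_scenarios()$current
  registry_config(n_patients = n, seed = seed,
                  hazard_params = list(transplant = sc$p_transplant,
                                       graft_failure = sc$p_graft_failure,
                                       death_post_tx = sc$p_death_post_tx),
                  ...)
}

test_that("registry generation is deterministic and validates its config", {
  cfg <- small_config(n = 200, seed = 7)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(r1, r2)
  r3 <- generate_registry(small_config(n = 200, seed = 8))
  expect_false(identical(r1, r3))

  expect_error(registry_config(n_patients = 0), "at least 1")
  expect_error(small_config(censor_horizon = -1), "positive")
  expect_error(registry_config(5, hazard_params = list(transplant = 1)),
               "must contain")
  bad <- small_config(n = 10)
  expect_error(weibull_ph_params(0.1, -2, 0), "positive")
})

test_that("registry records respect their structural invariants", {
  r <- generate_registry(small_config(n = 2000, seed = 3))
  tx <- !is.na(r$transplant_time)
  # donor fields present iff transplanted
  expect_identical(tx, !is.na(r$donor_age))
  expect_identical(tx, !is.na(r$donor_kdri))
  # times positive when present; scores positive
  for (col in c("transplant_time", "graft_failure_time", "death_time"))
    expect_true(all(r[[col]] > 0, na.rm = TRUE))
  expect_true(all(r$censor_time > 0))
  expect_true(all(r$epts > 0))
  expect_true(all(r$donor_kdri > 0, na.rm = TRUE))
  # at most one of graft failure / death observed per record
  expect_false(any(!is.na(r$graft_failure_time) & !is.na(r$death_time)))
  # observed events fall inside the administrative window
  expect_true(all(r$transplant_time < r$censor_time, na.rm = TRUE))
  expect_true(all(r$graft_failure_time < r$censor_time - r$transplant_time,
                  na.rm = TRUE))
  # EPTS and KDRI increase with age on average (monotone link)
  expect_gt(cor(r$age_at_listing, r$epts), 0.5)
  expect_gt(cor(r$donor_age[tx], r$donor_kdri[tx]), 0.5)
})

test_that("a zero transplant hazard leaves every patient untransplanted", {
  cfg <- small_config(n = 300, seed = 5)
  cfg$hazard_params$transplant <- weibull_ph_params(0, 1.5, -0.01)
  r <- generate_registry(cfg)
  expect_true(all(is.na(r$transplant_time)))
  expect_true(all(is.na(r$donor_age)))
  expect_true(all(is.na(r$donor_kdri)))
})

test_that("one-year graft-failure fraction matches the exponential closed form", {
  lam <- 0.15
  cfg <- small_config(n = 5000, seed = 12, censor_horizon = 40)
  cfg$hazard_params$transplant <- weibull_ph_params(2, 1, 0)      # transplant fast
  cfg$hazard_params$graft_failure <- weibull_ph_params(lam, 1, 0) # exponential
  cfg$hazard_params$death_post_tx <- weibull_ph_params(0, 1, 0)   # no competing death
  cfg$fixed_probs$death_waitlist <- 0
  r <- generate_registry(cfg)
  tx <- r[!is.na(r$transplant_time), ]
  # keep those with at least one year of post-transplant follow-up
  tx <- tx[tx$censor_time - tx$transplant_time >= 1, ]
  expect_gt(nrow(tx), 3000)
  phat <- mean(!is.na(tx$graft_failure_time) & tx$graft_failure_time <= 1)
  p <- 1 - exp(-lam)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / nrow(tx)))
})

test_that("generated survival converges to the specified Weibull law", {
  # transplant-time Kaplan-Meier vs the closed-form survival, beta = 0 so
  # the curve is age-free; administrative censoring handled by the KM
  cfg <- small_config(n = 20000, seed = 31)
  cfg$hazard_params$transplant <- weibull_ph_params(0.29, 1.54, 0)
  cfg$fixed_probs$death_waitlist <- 0
  r <- generate_registry(cfg)
  time <- ifelse(is.na(r$transplant_time), r$censor_time, r$transplant_time)
  event <- as.integer(!is.na(r$transplant_time))
  km <- survival::survfit(survival::Surv(time, event) ~ 1)
  S <- exp(-0.29 * km$time^1.54)
  expect_lt(max(abs(km$surv - S)), 0.02)
})

test_that("allocation options subset transplanted records by their pairing rules", {
  r <- generate_registry(small_config(n = 4000, seed = 21))
  expect_identical(apply_allocation_option(r, "current"), r)

  # hand-built records probing the thresholds
  probe <- r[rep(1L, 3), ]
  probe$transplant_time <- 1
  probe$age_at_listing <- c(40, 64, 30)
  probe$donor_kdri <- c(0.90, 1.80, 0.50)
  probe$epts <- c(2.0, 2.6, 0.90)
  probe$donor_age <- c(30, 60, 25)
  # best-quintile kidney paired with a non-best recipient: excluded
  expect_equal(nrow(apply_allocation_option(probe[1, ], "option1")), 0)
  # worst kidney to worst recipient: retained under option 2
  expect_equal(nrow(apply_allocation_option(probe[2, ], "option2")), 1)
  # donor 60 with recipient 65 at transplant: retained under option 4
  expect_equal(nrow(apply_allocation_option(probe[2, ], "option4")), 1)
  # young kidney to young recipient: retained under option 3
  expect_equal(nrow(apply_allocation_option(probe[3, ], "option3")), 1)

  expect_error(apply_allocation_option(r, "option9"), "unknown")

  for (opt in paste0("option", 1:4)) {
    sub <- apply_allocation_option(r, opt)
    # idempotent
    expect_identical(apply_allocation_option(sub, opt), sub)
    # untransplanted records pass through unchanged
    expect_equal(sum(is.na(sub$transplant_time)), sum(is.na(r$transplant_time)))
  }

  # the two complementary strata partition the retained transplanted set
  sub <- apply_allocation_option(r, "option1")
  stx <- sub[!is.na(sub$transplant_time), ]
  lo <- stx$donor_kdri <= 0.9148 & stx$epts <= 1.033
  hi <- stx$donor_kdri > 0.9148 & stx$epts > 1.033
  expect_true(all(xor(lo, hi)))

  # numeric option ids are accepted
  expect_identical(apply_allocation_option(r, 1), sub)
})

test_that("registry tables round-trip through CSV with empty-field missingness", {
  r <- generate_registry(small_config(n = 150, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(r, path)
  expect_false(any(grepl("NA", readLines(path), fixed = TRUE)))
  back <- read_registry(path)
  expect_equal(as.data.frame(back), as.data.frame(r), tolerance = 1e-12)
})

test_that("the dialysis cohort follows the configured annual mortality", {
  cfg <- small_config(n = 5000, seed = 17, censor_horizon = 30)
  d <- generate_dialysis_cohort(cfg)
  expect_true(all(d$time > 0))
  # among patients followed at least one year, the one-year death fraction
  # matches the annual probability within binomial error
  f <- d[d$time >= 1 | d$died == 1, ]
  one <- d$died == 1 & d$time <= 1
  atrisk <- d$time >= 1 | one
  phat <- sum(one) / sum(atrisk)
  expect_lt(abs(phat - 0.1091), 3 * sqrt(0.1091 * 0.8909 / sum(atrisk)))
})
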