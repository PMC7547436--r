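#' Configuration for the synthetic linked-registry generator
#'
#' Describes the statistical structure of the generated waitlist/transplant
#' registry: the three Weibull proportional-hazards event-time laws
#' (waitlist to transplant, transplant to graft failure, transplant to
#' death), the fixed annual probabilities driving waitlist and
#' post-graft-failure mortality as integer-year geometric processes, the
#' recipient and donor age distributions (truncated normal), the monotone
#' log-linear links (with lognormal noise) mapping recipient age to the
#' EPTS score and donor age to the KDRI score, and the administrative
#' censoring horizon of the study window.
#'
#' The default EPTS link is calibrated so that recipient ages 41 and 60
#' map to EPTS 1.033 and 2.4806, and the KDRI link so that donor ages 32
#' and 58 map to KDRI 0.9148 and 1.7208 — the allocation-rule thresholds
#' thus cut the generated scores at roughly the same quantiles as the ages
#' they are paired with, producing realistic overlap between the strata.
#'
#' @param n_patients Number of waitlisted patients (>= 1).
#' @param seed Integer seed; identical seeds give identical registries.
#' @param hazard_params Named list with [weibull_ph_params()] entries
#'   `transplant`, `graft_failure`, `death_post_tx`; defaults to the
#'   current-practice triples of [default_scenarios()].
#' @param fixed_probs Named list with annual probabilities
#'   `death_waitlist` and `death_post_gf`.
#' @param age_mean,age_sd,age_range Recipient age-at-listing distribution
#'   (truncated normal, years).
#' @param donor_age_sd,donor_age_range Donor age distribution; its mean is
#'   `45 + donor_age_assortativity * (recipient age - 50)`, giving mild
#'   assortative pairing under current practice.
#' @param donor_age_assortativity Slope of donor-age mean on recipient age.
#' @param epts_link,kdri_link Length-3 vectors `(intercept, slope, sdlog)`
#'   of the log-linear score links `score = exp(intercept + slope * age +
#'   N(0, sdlog))`.
#' @param censor_horizon Administrative censoring horizon in years from the
#'   study origin (> 0); listing times are uniform over the window.
#' @return An object of class `registry_config`.
#' @export
registry_config <- function(n_patients, seed = 1L,
                            hazard_params = NULL,
                            fixed_probs = list(death_waitlist = 0.0184,
                                               death_post_gf = 0.1091),
                            age_mean = 50, age_sd = 13, age_range = c(18, 80),
                            donor_age_sd = 14, donor_age_range = c(10, 80),
                            donor_age_assortativity = 0.3,
                            epts_link = c(intercept = -1.8594, slope = 0.046140, sdlog = 0.12),
                            kdri_link = c(intercept = -0.86645, slope = 0.024296, sdlog = 0.12),
                            censor_horizon = 11) {
  if (n_patients < 1) stop("'n_patients' must be at least 1")
  if (censor_horizon <= 0) stop("'censor_horizon' must be positive")
  if (is.null(hazard_params)) {
    cur <- default_scenarios()$current
    hazard_params <- list(transplant = cur$p_transplant,
                          graft_failure = cur$p_graft_failure,
                          death_post_tx = cur$p_death_post_tx)
  }
  needed <- c("transplant", "graft_failure", "death_post_tx")
  if (!all(needed %in% names(hazard_params)))
    stop("'hazard_params' must contain: ", paste(needed, collapse = ", "))
  for (nm in needed)
    if (!inherits(hazard_params[[nm]], "weibull_ph_params"))
      stop("'hazard_params$", nm, "' must be a weibull_ph_params object")
  for (nm in c("death_waitlist", "death_post_gf")) {
    p <- fixed_probs[[nm]]
    if (is.null(p) || p < 0 || p > 1)
      stop("'fixed_probs$", nm, "' must be a probability in [0, 1]")
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 hazard_params = hazard_params, fixed_probs = fixed_probs,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 donor_age_sd = donor_age_sd, donor_age_range = donor_age_range,
                 donor_age_assortativity = donor_age_assortativity,
                 epts_link = epts_link, kdri_link = kdri_link,
                 censor_horizon = censor_horizon),
            class = "registry_config")
}

#' @export
print.registry_config <- function(x, ...) {
  cat(sprintf("Registry config: %d patients, censoring at %g years, seed %d\n",
              x$n_patients, x$censor_horizon, x$seed))
  invisible(x)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd)),
               mean, sd)
}

# Latent event times under the Weibull PH law H(t) = lam e^(beta age) t^gamma,
# by inversion of the cumulative hazard; lam = 0 gives Inf (event never occurs).
rweibull_ph <- function(n, params, age) {
  scale <- params$lam * exp(params$beta_age * age)
  (stats::rexp(n) / scale)^(1 / params$gamma)
}

# Integer-year event times of an annual-probability process (geometric in
# years: the event falls in year k with probability p(1-p)^(k-1)).
rgeom_years <- function(n, p) {
  if (p == 0) rep(Inf, n) else stats::rgeom(n, p) + 1
}

#' Generate a synthetic linked waitlist/transplant registry
#'
#' Draws one patient-level dataset with the statistical structure the
#' cost-effectiveness analysis assumes: every patient is listed at a
#' uniform time in the study window; the waitlist competing events
#' (transplant via the Weibull transplant law evaluated at the patient's
#' age, death via the annual waitlist mortality as a geometric-in-years
#' process) and administrative censoring resolve by keeping the earliest,
#' with ties broken in favour of death; transplanted patients receive a
#' donor (age and KDRI) and post-transplant latent graft-failure and death
#' times from their Weibull laws, again resolved earliest-first against
#' censoring. EPTS and KDRI scores are monotone noisy functions of
#' recipient and donor age.
#'
#' @param config A [registry_config()].
#' @return A data frame, one row per patient, with columns `patient_id`,
#'   `age_at_listing`, `epts`, `listed_time`, `transplant_time` (years from
#'   listing, `NA` if untransplanted), `donor_age`, `donor_kdri` (present
#'   iff transplanted), `graft_failure_time`, `death_time` (years from
#'   transplant if transplanted, from listing otherwise), `censor_time`.
#'   See the data dictionary shipped at
#'   `system.file("extdata", "registry-dictionary.csv", package = "kidneyalloc")`.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n_patients

  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1L], config$age_range[2L])
  epts <- exp(config$epts_link[[1L]] + config$epts_link[[2L]] * age +
                stats::rnorm(n, 0, config$epts_link[[3L]]))
  listed <- stats::runif(n, 0, config$censor_horizon)
  censor <- config$censor_horizon - listed

  t_tx <- rweibull_ph(n, config$hazard_params$transplant, age)
  t_wld <- rgeom_years(n, config$fixed_probs$death_waitlist)

  # competing resolution on the waitlist; ties favour death
  died_wl <- t_wld <= pmin(t_tx, censor)
  transplanted <- !died_wl & t_tx < censor

  donor_age <- rep(NA_real_, n)
  kdri <- rep(NA_real_, n)
  gf_time <- rep(NA_real_, n)
  death_time <- rep(NA_real_, n)

  m <- sum(transplanted)
  if (m > 0) {
    da <- rtruncnorm(m, 45 + config$donor_age_assortativity * (age[transplanted] - 50),
                     config$donor_age_sd,
                     config$donor_age_range[1L], config$donor_age_range[2L])
    donor_age[transplanted] <- da
    kdri[transplanted] <- exp(config$kdri_link[[1L]] + config$kdri_link[[2L]] * da +
                                stats::rnorm(m, 0, config$kdri_link[[3L]]))
    t_gf <- rweibull_ph(m, config$hazard_params$graft_failure, age[transplanted])
    t_dtx <- rweibull_ph(m, config$hazard_params$death_post_tx, age[transplanted])
    censor_tx <- censor[transplanted] - t_tx[transplanted]
    dies <- t_dtx <= pmin(t_gf, censor_tx)      # ties favour death
    fails <- !dies & t_gf < censor_tx
    death_time[transplanted][dies] <- t_dtx[dies]
    gf_time[transplanted][fails] <- t_gf[fails]
  }
  death_time[died_wl] <- t_wld[died_wl]

  out <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age_at_listing = age,
    epts = epts,
    listed_time = listed,
    transplant_time = ifelse(transplanted, t_tx, NA_real_),
    donor_age = donor_age,
    donor_kdri = kdri,
    graft_failure_time = gf_time,
    death_time = death_time,
    censor_time = censor)
  class(out) <- c("registry_table", "data.frame")
  out
}

#' Generate a synthetic incident-dialysis cohort
#'
#' The second linked dataset of the analysis design: patients on dialysis
#' after graft failure, whose annual mortality follows the configured fixed
#' probability as a geometric-in-years process, censored administratively.
#' Used to exercise the cumulative-incidence estimation and
#' rate-to-probability conversion pipeline.
#'
#' @param config A [registry_config()]; `n_patients`, `seed`,
#'   `fixed_probs$death_post_gf` and `censor_horizon` are used.
#' @return A data frame with columns `patient_id`, `time` (years from
#'   dialysis start to death or censoring) and `died` (indicator).
#' @export
generate_dialysis_cohort <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)
  n <- config$n_patients
  t_death <- rgeom_years(n, config$fixed_probs$death_post_gf)
  censor <- stats::runif(n, 0, config$censor_horizon)
  died <- t_death <= censor
  data.frame(patient_id = sprintf("D%06d", seq_len(n)),
             time = pmin(t_death, censor),
             died = as.integer(died))
}

allocation_rules <- list(
  option1 = function(kdri, epts, donor_age, age_tx)
    (kdri <= 0.9148 & epts <= 1.033) | (kdri > 0.9148 & epts > 1.033),
  option2 = function(kdri, epts, donor_age, age_tx)
    (kdri >= 1.7208 & epts >= 2.4806) | (kdri < 1.7208 & epts < 2.4806),
  option3 = function(kdri, epts, donor_age, age_tx)
    (donor_age <= 32 & age_tx <= 41) | (donor_age > 32 & age_tx > 41),
  option4 = function(kdri, epts, donor_age, age_tx)
    (donor_age >= 58 & age_tx >= 60) | (donor_age < 58 & age_tx < 60)
)

#' Subset a registry according to a hypothetical allocation option
#'
#' Each option pairs a donor-quality stratum with a recipient-quality
#' stratum; transplanted records whose donor/recipient pairing violates
#' the option's rule are excluded (not reassigned), mirroring how the
#' per-option analysis datasets are formed from the full registry.
#' Untransplanted records pass through unchanged; `"current"` is the
#' identity.
#'
#' Rules: option 1 keeps best-quintile kidneys (KDRI <= 0.9148) with
#' best-quintile recipients (EPTS <= 1.033) and the complements together;
#' option 2 keeps worst-quintile kidneys (KDRI >= 1.7208) with
#' worst-quintile recipients (EPTS >= 2.4806) and the complements;
#' option 3 pairs youngest-quartile donors (age <= 32) with youngest
#' recipients (age at transplant <= 41); option 4 pairs oldest-quartile
#' donors (age >= 58) with oldest recipients (age at transplant >= 60).
#'
#' @param records A registry data frame from [generate_registry()].
#' @param option One of `"current"`, `"option1"` .. `"option4"` (the bare
#'   numbers 1-4 are also accepted).
#' @return The retained subset, same columns.
#' @export
apply_allocation_option <- function(records, option) {
  option <- as.character(option)
  if (option %in% as.character(1:4)) option <- paste0("option", option)
  if (option == "current") return(records)
  rule <- allocation_rules[[option]]
  if (is.null(rule))
    stop("unknown allocation option: '", option,
         "' (expected current or option1..option4)")
  tx <- !is.na(records$transplant_time)
  age_tx <- records$age_at_listing + records$transplant_time
  ok <- rule(records$donor_kdri, records$epts, records$donor_age, age_tx)
  keep <- !tx | (tx & !is.na(ok) & ok)
  records[keep, , drop = FALSE]
}

#' Write a registry table to CSV
#'
#' One row per patient, missing values as empty fields; round-trips
#' loss-free through [read_registry()].
#'
#' @param records Registry data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a registry table written by [write_registry()]
#'
#' @param path CSV path.
#' @return Registry data frame.
#' @export
read_registry <- function(path) {
  out <- utils::read.csv(path, na.strings = "",
                         colClasses = c(patient_id = "character"))
  num_cols <- setdiff(names(out), "patient_id")
  out[num_cols] <- lapply(out[num_cols], as.numeric)
  class(out) <- c("registry_table", "data.frame")
  out
}
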