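# Default model parameters: Weibull proportional-hazards triples per
# allocation option and transition (estimated by Weibull regression on linked
# registry data, age as covariate), shared fixed annual probabilities, state
# utilities and 2018 AUD costs.
#
# Note: the current-practice graft-failure age coefficient circulates in the
# source parameter table as +0.020; that sign is inconsistent with the other
# four options and with the published cohort totals (it triples the baseline
# graft-failure hazard at age 50), so -0.020 is used here.
options:
  current:
    transplant:        {lam: 0.2898, gamma: 1.5440, beta_age: -0.009, sem_lam: 0.0184, sem_gamma: 0.0188, sem_beta: 0.0011}
    graft_failure:     {lam: 0.1662, gamma: 0.4424, beta_age: -0.020, sem_lam: 0.0199, sem_gamma: 0.0158, sem_beta: 0.0025}
    death_post_tx:     {lam: 0.0020, gamma: 0.9348, beta_age: 0.0475, sem_lam: 0.0004, sem_gamma: 0.0313, sem_beta: 0.0036}
  option1:
    transplant:        {lam: 0.2194, gamma: 1.6090, beta_age: -0.006, sem_lam: 0.0225, sem_gamma: 0.0237, sem_beta: 0.0017}
    graft_failure:     {lam: 0.2018, gamma: 0.4178, beta_age: -0.021, sem_lam: 0.0359, sem_gamma: 0.0180, sem_beta: 0.0034}
    death_post_tx:     {lam: 0.0023, gamma: 0.9410, beta_age: 0.0465, sem_lam: 0.0007, sem_gamma: 0.0353, sem_beta: 0.0046}
  option2:
    transplant:        {lam: 0.3148, gamma: 1.4810, beta_age: -0.008, sem_lam: 0.0222, sem_gamma: 0.0217, sem_beta: 0.0013}
    graft_failure:     {lam: 0.1307, gamma: 0.4898, beta_age: -0.019, sem_lam: 0.0187, sem_gamma: 0.0212, sem_beta: 0.0031}
    death_post_tx:     {lam: 0.0022, gamma: 0.8720, beta_age: 0.0457, sem_lam: 0.0006, sem_gamma: 0.0396, sem_beta: 0.0046}
  option3:
    transplant:        {lam: 0.3102, gamma: 1.5982, beta_age: -0.011, sem_lam: 0.0292, sem_gamma: 0.0235, sem_beta: 0.0016}
    graft_failure:     {lam: 0.1219, gamma: 0.4081, beta_age: -0.013, sem_lam: 0.0232, sem_gamma: 0.0185, sem_beta: 0.0036}
    death_post_tx:     {lam: 0.0021, gamma: 0.9407, beta_age: 0.0479, sem_lam: 0.0006, sem_gamma: 0.0357, sem_beta: 0.0046}
  option4:
    transplant:        {lam: 0.3387, gamma: 1.4900, beta_age: -0.010, sem_lam: 0.0243, sem_gamma: 0.0227, sem_beta: 0.0014}
    graft_failure:     {lam: 0.1173, gamma: 0.4536, beta_age: -0.015, sem_lam: 0.0179, sem_gamma: 0.0204, sem_beta: 0.0033}
    death_post_tx:     {lam: 0.0018, gamma: 0.8841, beta_age: 0.0521, sem_lam: 0.0005, sem_gamma: 0.0392, sem_beta: 0.0046}
shared:
  death_waitlist:      {p: 0.0184, sem: 0.0003}
  death_post_gf:       {p: 0.1091, sem: 0.0006}
  cost_aud_2018:
    tx_year1:          {value: 99968.00, uncertainty_fraction: 0.15}
    tx_subsequent:     {value: 13916.00, uncertainty_fraction: 0.15}
    dialysis:          {value: 81689.34, uncertainty_fraction: 0.15}
  utility:
    transplant:        {value: 0.82, ci_low: 0.74, ci_high: 0.90}
    dialysis:          {value: 0.70, ci_low: 0.62, ci_high: 0.78}
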