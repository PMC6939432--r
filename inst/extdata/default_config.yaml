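# Default model configuration: every value is the published base-case input.
# Units: costs in 2015 CNY; ages in years; BMI in kg/m^2; FPG in mmol/L;
# HbA1c in %; probabilities and utilities dimensionless; rate per year.
cohort:
  sample_size: {surgery: 134, medication: 81}
  covariates:
    - {variable: age,   surgery_mean: 39.05, surgery_sd: 12.03, medication_mean: 42.54, medication_sd: 12.04}
    - {variable: bmi,   surgery_mean: 36.47, surgery_sd: 8.15,  medication_mean: 33.65, medication_sd: 4.12}
    - {variable: fpg,   surgery_mean: 9.74,  surgery_sd: 2.98,  medication_mean: 8.91,  medication_sd: 2.31}
    - {variable: hba1c, surgery_mean: 8.49,  surgery_sd: 1.46,  medication_mean: 7.93,  medication_sd: 1.84}
  females: {surgery: 65, medication: 27}
  # 2-year remission: 71/134 surgery, 4/81 medication; no deaths observed
  p_remission: {surgery: 0.529850746268657, medication: 0.049382716049383}
psm:
  covariates: [sex, age, bmi, fpg, hba1c]
  caliper: 0.03
  # when true, the matched cohort's remission fractions replace the
  # markov init_remission values below
  use_matched_init: false
markov:
  p_relapse: 0.0025       # annual remission -> t2dm relapse
  mu_remission: 0.0062    # annual mortality, remission (non-diabetic)
  mu_t2dm: 0.0204         # annual mortality, t2dm
  horizon: 40             # transition cycles (years)
  # matched-cohort 2-year outcome shares: 22/41 and 1/41 in remission
  init_remission: {surgery: 0.536585365853659, medication: 0.024390243902439}
economics:
  costs:
    surgery_initial: 46404.41
    surgery_cycle: 2766.41
    medication_initial: 12581.46
    medication_cycle: 7674.24
  utilities: {remission: 0.95, t2dm: 0.77}
  rate: 0.05              # annual discount, applied beyond the first year
sensitivity:
  n_draws: 1000
  wtp: 193932             # 3x GDP per capita, CNY/QALY
  wtp_grid_max: 400000
  wtp_grid_step: 10000
seed: 42
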