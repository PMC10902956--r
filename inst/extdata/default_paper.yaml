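# Default model configuration: published base case, DRd vs KRd in RRMM.
# Costs are USD (2022-08-10 price basis); cycle length is one month.

settings:
  cycle_length_months: 1
  horizon_cycles: 120
  wtp_per_qaly: 1290          # 40,000,000 IRR per QALY expressed in USD
  discount_cost_annual: 0.072
  discount_outcome_annual: 0.03
  discount_ly: false          # life-years reported undiscounted
  half_cycle_correction: false

# Every uncertain quantity: mean, 95% CI, sampling family, role.
# family: fixed parameters are excluded from DSA and PSA.
parameters:
  - {name: age_years,              mean: 69,     low: .na, high: .na,   family: fixed,     role: rate}
  - {name: male_fraction,          mean: 0.59,   low: .na, high: .na,   family: fixed,     role: share}
  - {name: p_ae_drd,               mean: 0.011,  low: 0.009,  high: 0.0126, family: beta,  role: probability-per-cycle}
  - {name: p_ae_krd,               mean: 0.026,  low: 0.0221, high: 0.0299, family: beta,  role: probability-per-cycle}
  - {name: cost_specialist_visit,  mean: 2.08,   low: 1.66,   high: 2.5,    family: gamma, role: cost-USD}
  - {name: cost_lab_tests,         mean: 20,     low: 16,     high: 24,     family: gamma, role: cost-USD}
  - {name: cost_mri,               mean: 10.4,   low: 8.33,   high: 12.5,   family: gamma, role: cost-USD}
  - {name: cost_ct,                mean: 11.8,   low: 9.4,    high: 14.4,   family: gamma, role: cost-USD}
  - {name: cost_daratumumab_400mg, mean: 274.2,  low: 219.4,  high: 329,    family: gamma, role: cost-USD}
  - {name: cost_carfilzomib_60mg,  mean: 217,    low: 173,    high: 260,    family: gamma, role: cost-USD}
  - {name: cost_dexamethasone_40mg, mean: 0.83,  low: 0.66,   high: 1,      family: gamma, role: cost-USD}
  - {name: cost_radiotherapy,      mean: 14.2,   low: 11.4,   high: 17,     family: gamma, role: cost-USD}
  - {name: cost_lenalidomide_25mg, mean: 2.9,    low: 2.3,    high: 3.5,    family: gamma, role: cost-USD}
  - {name: cost_drug_administration, mean: 19.7, low: 15.8,   high: 23.6,   family: gamma, role: cost-USD}
  - {name: cost_management_toxicity, mean: 21.6, low: 16.4,   high: 25.1,   family: gamma, role: cost-USD}
  - {name: cost_ae,                mean: 24.4,   low: 19.5,   high: 29.2,   family: gamma, role: cost-USD}
  - {name: u_pfs,                  mean: 0.73,   low: 0.584,  high: 0.876,  family: beta,  role: utility}
  - {name: du_ae,                  mean: -0.049, low: -0.0588, high: -0.0392, family: beta, role: disutility}
  - {name: du_progression,         mean: -0.054, low: -0.0648, high: -0.0432, family: beta, role: disutility}
  - {name: hr_pfs,                 mean: 0.60,   low: 0.43,   high: 0.82,   family: lognormal, role: hazard-ratio}
  - {name: hr_os,                  mean: 0.46,   low: 0.28,   high: 0.75,   family: lognormal, role: hazard-ratio}

# Treatment strategies.  The comparator (KRd) carries the baseline
# hazards; the intervention (DRd) modifies them through hazard ratios.
arms:
  drd:
    label: "Daratumumab + lenalidomide + dexamethasone (DRd)"
    planned_duration_cycles: 25
    ae_prob: p_ae_drd
    hr_pfs: hr_pfs
    hr_os: hr_os
    drugs:
      - {drug: daratumumab,  calendar: daratumumab,  unit_cost: cost_daratumumab_400mg,  units_per_administration: 1}
      - {drug: lenalidomide, calendar: lenalidomide, unit_cost: cost_lenalidomide_25mg,  units_per_administration: 1}
      - {drug: dexamethasone, calendar: dexamethasone, unit_cost: cost_dexamethasone_40mg, units_per_administration: 1}
  krd:
    label: "Carfilzomib + lenalidomide + dexamethasone (KRd)"
    planned_duration_cycles: 18
    ae_prob: p_ae_krd
    hr_pfs: ~
    hr_os: ~
    drugs:
      - {drug: carfilzomib,  calendar: carfilzomib,  unit_cost: cost_carfilzomib_60mg,   units_per_administration: 1}
      - {drug: lenalidomide, calendar: lenalidomide, unit_cost: cost_lenalidomide_25mg,  units_per_administration: 1}
      - {drug: dexamethasone, calendar: dexamethasone, unit_cost: cost_dexamethasone_40mg, units_per_administration: 1}

# Cost composition.  Component lists reference parameter names and are
# summed per cycle (or per event for adverse events).
costs:
  administration_per_cycle: cost_drug_administration
  monitoring_on_treatment: [cost_specialist_visit, cost_lab_tests]
  pfs_post_treatment: [cost_specialist_visit, cost_lab_tests]
  pd_per_cycle: [cost_specialist_visit, cost_lab_tests, cost_mri, cost_ct, cost_radiotherapy]
  ae_event: [cost_ae, cost_management_toxicity]
  # Per-arm scale factor applied to every cost component of the arm.
  # With calibrate_to_totals true, the scales are solved so that each
  # arm's discounted lifetime cost equals total_cost_targets.
  cost_scale: {drd: 1.0, krd: 1.0}
  calibrate_to_totals: true
  total_cost_targets: {drd: 15370, krd: 15106}

calibration:
  target_ly_krd: 3.52           # undiscounted restricted life-years, comparator arm
  median_ttp_months: 26         # fixes the baseline progression hazard
  pd_mortality_ratio: 2.0       # post-progression vs progression-free death hazard
  apply_hr_pfs_to_death: false  # if true, HR_PFS also scales PFS -> Death
  bracket: [1.0e-06, 5.0]       # monthly mortality-hazard bracket for root finding

psa:
  n_draws: 10000
  vary_hazard_ratios: true
  vary_utilities: true
  seed: 20220810

bia:
  population_2022: 85345667
  population_2023: 86369815     # annual growth derived from the 2022 -> 2023 ratio
  years: 5
  incidence_per_100k: 1.8
  prevalence_per_100k: 3.27
  mm_patients_2022: 4267        # printed anchor; scaled with population growth
  adjusted_patients_2022: 3456  # after death-rate adjustment
  eligible_fraction: 0.20
  market_share_drd: [0.05, 0.10, 0.15, 0.20, 0.25]
  scenario1_cost_2022: 10258397 # without-DRd spending anchor, year 1
  scenario2_cost_2022: 10656889 # with-DRd spending anchor, year 1
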