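cohort:
  mean_age_years: 39.6
  mean_weight_kg: 75.37
  fraction_female: 0.427
clinical:
  soc_response_wk8:
    value: 0.25
    low: 0.2
    high: 0.31
  rr_response_wk8:
    value: 1.34
    low: 1.02
    high: 1.77
  soc_remission_wk8:
    value: 0.09
    low: 0.06
    high: 0.13
  rr_remission_wk8:
    value: 1.77
    low: 1.1
    high: 2.86
  soc_response_percycle:
    value: 0.016
    low: 0.01
    high: 0.023
  rr_response_percycle:
    value: 1.32
    low: 0.8
    high: 2.18
  soc_remission_percycle:
    value: 0.014
    low: 0.009
    high: 0.02
  rr_remission_percycle:
    value: 2.03
    low: 1.24
    high: 3.32
  loss_response_percycle_ada: 0.161
  loss_response_percycle_soc: 0.158
  loss_remission_percycle_ada: 0.0
  loss_remission_percycle_soc: 0.016
  surgery_annual_soc: 0.0475
  rr_surgery_ada:
    value: 0.77
    low: 0.33
    high: 1.86
  complication_prob:
    value: 0.53
    low: 0.27
    high: 0.53
  ae_discontinuation_percycle: 0.0
utilities:
  active_treatment:
    value: 0.42
    low: 0.32
  remission:
    value: 0.88
    low: 0.79
    high: 0.91
  response:
    value: 0.76
    low: 0.58
    high: 0.94
  remission_after_surgery: 0.61
  complications_after_surgery:
    value: 0.42
    high: 0.49
costs:
  ada_price_per_mg: 54.55
  azathioprine_per_mg: 0.0107
  prednisolone_per_mg: 0.1055
  mesalazine_per_mg: 0.0015
  mercaptopurine_per_mg: 0.0166
  monitoring_per_8wk: 121.56
  monitoring_per_1wk: 15.2
  administration_once: 468.0
  surgery:
    value: 12480.0
    low: 6240.0
    high: 37440.0
  complication_treatment: 4160.0
  standard_care_per_8wk: 204.32
  standard_care_per_1wk: 25.54
  indirect_annual_remission: 6523.75
  indirect_annual_active: 22934.580000000002
  eur_per_pln: 4.2
settings:
  horizon_years: 0.307692307692
  discount_rate_costs: 0.0
  discount_rate_effects: 0.0
  treatment_cap_weeks: 52.0
  induction_weeks: 8
  maintenance_cycle_weeks: 8
  seed: 1
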