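setting: US
population: all_randomized
model:
  cycle_days: 21.0
  horizon_years: 10.0
  annual_discount: 0.03
  wtp: 100000.0
  bsa: 2.1
  nivo_max_years: 2.0
survival:
  comparator:
    pfs_median: 6.9
    os_median: 11.6
  intervention:
    pfs_median: 7.7
    os_median: 13.8
  hr:
    pfs: 0.77
    os: 0.8
  source: medians
  intervention_source: hazard_ratio
  family: exponential
regimens:
  backbone: XELOX
  pd_regimen: ~
utilities:
  u_pfs: 0.797
  u_pd: 0.577
ae_incidence:
  intervention:
    anemia: 0.06
    neutropenia: 0.15
    neutrophil_count_decreased: 0.11
  comparator:
    anemia: 0.03
    neutropenia: 0.12
    neutrophil_count_decreased: 0.08
overrides:
  drug_price_multiplier: []
  unit_cost: []
  ae_cost: []
psa:
  'n': 1000.0
  seed: 2.0230913e+07
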