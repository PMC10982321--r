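funnel:
  base_population: 6795374
  stages:
    angina_pectoris: 0.0361673985861558147659
    refractory_angina: 0.1199999999999999955591
    reducer_eligible: 0.5999999999999999777955
current_mix:
  device_share_year1: 0.0100000000000000002082
  annual_increment: 0.0
  years: 5
revised_mix:
  device_share_year1: 0.0149999999999999994449
  annual_increment: 0.0035000000000000000729
  years: 5
costs:
  reducer_implant: 7000.0
  elective_pci: 6434.0
  hospitalization: 1870.0
  outpatient_visit: 88.0600000000000022737368
  ed_admission: 193.0
  coronarography: 2142.0
drugs:
  name:
  - beta_blockers
  - calcium_channel_blockers
  - nitrates
  - ivabradine
  - ranolazine
  annual_cost:
  - 27.2899999999999991473487
  - 114.0400000000000062527761
  - 37.4099999999999965893949
  - 78.1899999999999977262632
  - 827.3200000000000500222086
  usage_rate:
  - 0.7820000000000000284217
  - 0.545000000000000039968
  - 0.6650000000000000355271
  - 0.1809999999999999942268
  - 0.3190000000000000057732
hru:
  reducer:
    hospitalizations: 1.0
    ed_admissions: 0.1000000000000000055511
    coronarographies: 0.2000000000000000111022
    outpatient_visits: 0.6999999999999999555911
    pci: 0.1000000000000000055511
  soc:
    hospitalizations: 3.3999999999999999111822
    ed_admissions: 0.2000000000000000111022
    coronarographies: 1.0
    outpatient_visits: 2.1000000000000000888178
    pci: 0.2999999999999999888978
  distribution: normal
tree:
  cohort_size: 10000
  p_success: 0.9451000000000000511591
  utility_success: 0.5939999999999999724665
  utility_soc: 0.4560000000000000164313
  annual_survival:
    reducer:
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    soc:
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
  annual_cost_reducer_year1: 15702.0
  annual_cost_reducer_later: 2550.0
  annual_cost_soc: 6988.0
discount:
  rate: 0.0350000000000000033307
  apply_to_costs: yes
  apply_to_outcomes: yes
  first_year_discounted: no
uncertainty:
  relative_sd: 0.1499999999999999944489
  n_draws: 1000
  seed: 1234
  dsa_delta: 0.1499999999999999944489
horizon_years: 5
annual_incident_eligible: 0.0
annual_mortality: 0.0
drug_reduction_on_reducer: 0.0
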