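parameters:
  discount_rate_costs:
    value: 0.05
    distribution: beta
    range:
    - 0.02
    - 0.1
  discount_rate_outcomes:
    value: 0.05
    distribution: beta
    range:
    - 0.03
    - 0.08
  q60_background:
    value: 0.0095
  hr_sarcopenia_mortality:
    value: 1.6
    distribution: lognormal
    ci95:
    - 1.24
    - 2.06
  rr_fracture_mortality_y1:
    value: 6.57
    distribution: lognormal
    ci95:
    - 5.54
    - 7.29
  p_fall:
    value: 0.155
    distribution: beta
    sd: 0.041
  p_fracture_given_fall:
    value: 0.33
    distribution: beta
    sd: 0.06
  utility_sarcopenic:
    value: 0.785
    distribution: beta
    sd: 0.1962
  disutility_fracture_y1:
    value: 0.25
    distribution: beta
    sd: 0.025
  disutility_post_fracture:
    value: 0.17
    distribution: beta
    sd: 0.017
  cost_fracture_y1:
    value: 12588.213999999999942
    distribution: gamma
    sd: 3147.052999999999884
  cost_post_fracture:
    value: 2517.639999999999873
    distribution: gamma
    sd: 503.0
  cost_visits_labs:
    value: 400.408999999999992
  wtp:
    value: 25249.130000000001019
  ppp_rial_per_dollar:
    value: 29704.0
strategies:
- name: None
  dosage_note: no intervention
  acceptance: 0.9
  annual_cost:
    value: 0.0
- name: E
  dosage_note: 3 training sessions of 1.5 h per week
  acceptance: 0.9
  annual_cost:
    value: 4268.784999999999854
    distribution: gamma
    sd: 853.75
  frr_mm:
    value: 14.0
    distribution: beta
    sd: 3.5
    support:
    - 0.0
    - 100.0
- name: P
  dosage_note: Whey protein 45 g/day
  acceptance: 0.9
  annual_cost:
    value: 5463.328999999999724
    distribution: gamma
    sd: 1515.555000000000064
  frr_mm:
    value: 3.64
    distribution: beta
    sd: 0.91
    support:
    - 0.0
    - 100.0
  frr_ms:
    value: 1.6
    distribution: beta
    sd: 0.4
    support:
    - 0.0
    - 100.0
  frr_mp:
    value: 8.82
    distribution: beta
    sd: 2.205
    support:
    - 0.0
    - 100.0
- name: D
  dosage_note: Vitamin D 800 IU/day
  acceptance: 0.9
  annual_cost:
    value: 129.27600000000001
    distribution: gamma
    sd: 25.8552
  frr_mp:
    value: 27.079999999999998
    distribution: beta
    sd: 6.77
    support:
    - 0.0
    - 100.0
- name: WBV
  dosage_note: 3 sessions per week
  acceptance: 0.9
  annual_cost:
    value: 7126.311999999999898
    distribution: gamma
    sd: 1790.565000000000055
  frr_ms:
    value: 1.15
    distribution: beta
    sd: 0.2875
    support:
    - 0.0
    - 100.0
  frr_mp:
    value: 33.229999999999997
    distribution: beta
    sd: 8.307499999999999
    support:
    - 0.0
    - 100.0
- name: P+D
  dosage_note: Vitamin D 800 IU/day + Whey protein 45 g/day
  acceptance: 0.9
  annual_cost:
    value: 5592.604999999999563
    distribution: gamma
    sd: 1536.56899999999996
  frr_mm:
    value: 46.520000000000003
    distribution: beta
    sd: 11.630000000000001
    support:
    - 0.0
    - 100.0
  frr_ms:
    value: 1.6
    distribution: beta
    sd: 0.4
    support:
    - 0.0
    - 100.0
  frr_mp:
    value: 20.100000000000001
    distribution: beta
    sd: 5.025
    support:
    - 0.0
    - 100.0
- name: D+E
  dosage_note: Vitamin D 800 IU/day + 3 training sessions of 1.5 h per week
  acceptance: 0.9
  annual_cost:
    value: 4398.0600000000004
    distribution: gamma
    sd: 1662.537000000000035
  frr_mm:
    value: 15.31
    distribution: beta
    sd: 3.8275
    support:
    - 0.0
    - 100.0
  frr_ms:
    value: 3.7
    distribution: beta
    sd: 0.925
    support:
    - 0.0
    - 100.0
- name: P+D+E
  dosage_note: Whey protein 45 g/day + Vitamin D 800 IU/day + 3 training sessions
    of 1.5 h per week
  acceptance: 0.9
  annual_cost:
    value: 9861.389999999999418
    distribution: gamma
    sd: 7477.532000000000153
  frr_mm:
    value: 24.350000000000001
    distribution: beta
    sd: 6.0875
    support:
    - 0.0
    - 100.0
  frr_ms:
    value: 3.85
    distribution: beta
    sd: 0.962
    support:
    - 0.0
    - 100.0
  frr_mp:
    value: 37.329999999999998
    distribution: beta
    sd: 9.332000000000001
    support:
    - 0.0
    - 100.0
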