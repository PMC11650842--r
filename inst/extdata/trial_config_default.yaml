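n_clusters: 30
clusters_per_arm: 15
n_intervention: 238
n_control: 243
age_mean: 54.4
age_sd: 9.4
age_range:
- 30.0
- 70.0
prop_male: 0.528
prop_semi_urban: 0.642
baseline_utility_mean: 0.9
baseline_utility_sd: 0.13
followup_control_mean: 0.7908
utility_effect: 0.03
followup_tracking: 0.4
followup_innovation_sd: 0.3
utility_floor: -0.594
cluster_utility_sd: 0.0
vas_mean: 70.0
vas_sd: 15.0
cost_component_params:
  category:
  - consultation
  - screening
  - medication
  - inpatient
  - transport
  - food
  - indirect_income_loss
  - intervention_phone
  - intervention_peer
  - intervention_training
  - consultation
  - screening
  - medication
  - inpatient
  - transport
  - food
  - indirect_income_loss
  - intervention_phone
  - intervention_peer
  - intervention_training
  arm:
  - intervention
  - intervention
  - intervention
  - intervention
  - intervention
  - intervention
  - intervention
  - intervention
  - intervention
  - intervention
  - control
  - control
  - control
  - control
  - control
  - control
  - control
  - control
  - control
  - control
  mean:
  - 4.16
  - 14.31
  - 9.35
  - 2.8
  - 0.64
  - 1.62
  - 12.83
  - 0.47
  - 2.53
  - 14.33
  - 3.85
  - 13.43
  - 3.68
  - 1.45
  - 0.66
  - 2.06
  - 9.11
  - 0.0
  - 0.0
  - 0.0
  sd:
  - 6.28
  - 6.12
  - 17.73
  - 30.47
  - 0.77
  - 2.18
  - 24.88
  - 0.08
  - 1.37
  - 7.27
  - 7.05
  - 5.88
  - 8.4
  - 4.68
  - 0.68
  - 2.11
  - 6.55
  - 0.0
  - 0.0
  - 0.0
missingness_rate: 0.079
horizon: 0.5
seed: 1
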