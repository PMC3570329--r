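# Example simulation config. Omitted fields keep the package defaults
# (see ?sim_config).
n_patients: 1681
seed: 1
sex_male_prob: 0.434
days_supply_median: 30
age_group_probs: [0.036, 0.170, 0.307, 0.437, 0.050]
comorbidity_prevalences:
  hypertension: 0.501
  heart_disease: 0.413
  respiratory_illness: 0.339
  diabetes: 0.327
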