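# Synthetic merged-race (3-level) variant of the PLCOm2012 model: the
# Asian, Hispanic, and Native Hawaiian/Other Pacific Islander categories
# are merged into the White reference (race coefficient 0); all other
# terms are identical to plcom2012_original. This file is a derived
# stand-in constructed by category merging, not a re-fitted coefficient
# set.
schema_version: 1
model_name: plcom2012_race3l
merged_race_variant: true
intercept: -4.532506
terms:
  - variable: age
    transformation: center
    center: 62
    coefficient: 0.0778868
  - variable: education
    transformation: center
    center: 4
    coefficient: -0.0812744
  - variable: bmi
    transformation: center
    center: 27
    coefficient: -0.0274194
  - variable: copd_emphysema
    transformation: identity
    coefficient: 0.3553063
  - variable: personal_cancer_history
    transformation: identity
    coefficient: 0.4589971
  - variable: family_history_lung_cancer
    transformation: identity
    coefficient: 0.587185
  - variable: smoking_status
    transformation: indicator
    level: current
    coefficient: 0.2597431
  - variable: intensity
    transformation: reciprocal_scaled
    scale: 10
    center: 0.4021541613
    coefficient: -1.822606
  - variable: duration
    transformation: center
    center: 27
    coefficient: 0.0317321
  - variable: quit_years
    transformation: center
    center: 10
    coefficient: -0.0308572
race_coefficients:
  white: 0.0
  african_american: 0.3944778
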