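gp: 20.92
internist: 68.06
psychiatrist: 46.55
psychotherapist: 81.44
other_specialist: 40.0
inpatient_mental: 335.52
inpatient_psychosomatic: 306.41
daycare: 150.0
travel: 0.3
informal_care: 18.33
domestic_help: 18.33
opportunity_cost: 23.1
intervention_cost: 299.0
control_program_cost: 10.0
statutory_share: 0.89
cpi_index_factor: 1.04
euro_to_gbp: 0.85
antidepressant_packages:
  price_statutory:
  - 16.5
  - 28.9
  - 46.8
  price_private:
  - 19.8
  - 33.5
  - 53.9
  ddd:
  - 50.0
  - 100.0
  - 100.0
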