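# Additive AKI risk score: factor weights in points.
# The eligibility threshold of 6 points is fixed by the trial design;
# these factor weights are documented placeholders standing in for a
# published prediction score whose exact point values are distributed in
# trial supplements. Replace with site-validated weights before use on
# real screening data.
threshold: 6
weights:
  sepsis: 3
  vasopressors: 3
  mechanical_ventilation: 2
  major_surgery: 2
  chronic_kidney_disease: 2
  nephrotoxin_exposure: 2
  diabetes: 1
  age_over_65: 1
  liver_disease: 1
  anemia: 1
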