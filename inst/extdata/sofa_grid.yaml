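# Standard six-organ SOFA grid; four thresholds per organ give
# subscores 1-4 (0 when none is crossed).
# direction "low": thresholds crossed downward (value < cut);
# direction "high": crossed upward (value > cut);
# "category": the input is already an ordinal 0-4 subscore
# (used for the MAP / vasopressor cardiovascular axis).
respiration:       {direction: low,      cuts: [400, 300, 200, 100]}   # PaO2/FiO2, mmHg
coagulation:       {direction: low,      cuts: [150, 100, 50, 20]}     # platelets, 10^3/uL
liver:             {direction: high,     cuts: [1.2, 2.0, 6.0, 12.0]}  # bilirubin, mg/dL
cardiovascular:    {direction: category, cuts: [0, 1, 2, 3, 4]}
cns:               {direction: low,      cuts: [15, 13, 10, 6]}        # Glasgow Coma Scale
renal:             {direction: high,     cuts: [1.2, 2.0, 3.5, 5.0]}   # creatinine, mg/dL
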