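# Clinical thresholds defining the unhealthy range of each ALI component.
# Direction is the comparison applied to the measured value; a value
# satisfying it is UNHEALTHY. Creatinine clearance (CC) is the only
# sex-specific rule. Serum albumin is deliberately kept as printed in the
# source threshold table (>= 3.5) even though low albumin is the
# conventional risk direction; edit here to explore alternatives.
SBP:
  direction: greater
  cutoff: 140
  units: mmHg
DBP:
  direction: greater
  cutoff: 90
  units: mmHg
BMI:
  direction: greater
  cutoff: 30
  units: kg/m2
TRIG:
  direction: greater_equal
  cutoff: 150
  units: mg/dL
CHOL:
  direction: greater_equal
  cutoff: 200
  units: mg/dL
CRP:
  direction: greater_equal
  cutoff: 10
  units: mg/L
HBA1C:
  direction: greater_equal
  cutoff: 6.5
  units: percent
ALB:
  direction: greater_equal
  cutoff: 3.5
  units: g/dL
CC:
  direction: less
  cutoff:
    male: 110
    female: 100
  units: mL/min
HCST:
  direction: greater
  cutoff: 50
  units: umol/L
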