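pH:
  unit: ''
  weight: 1.0
  curve:
    conc:
    - 2.0
    - 5.0
    - 6.0
    - 6.5
    - 7.0
    - 8.0
    - 8.5
    - 9.0
    - 10.0
    - 12.0
    ci:
    - 0.0
    - 40.0
    - 80.0
    - 90.0
    - 100.0
    - 100.0
    - 90.0
    - 80.0
    - 40.0
    - 0.0
    interpolation: linear
  class_standards:
    low: 6.0
    high: 9.0
  direction: range
  mdl: 0.0
WT:
  unit: degC
  weight: 1.0
  curve:
    conc:
    - 0.0
    - 5.0
    - 10.0
    - 15.0
    - 22.0
    - 28.0
    - 32.0
    - 40.0
    ci:
    - 60.0
    - 70.0
    - 85.0
    - 95.0
    - 100.0
    - 80.0
    - 50.0
    - 0.0
    interpolation: linear
  class_standards: ~
  direction: above
  mdl: 0.0
DO:
  unit: mg/L
  weight: 4.0
  curve:
    conc:
    - 0.0
    - 1.0
    - 2.0
    - 3.0
    - 4.0
    - 5.0
    - 6.0
    - 7.5
    - 9.0
    ci:
    - 0.0
    - 10.0
    - 20.0
    - 35.0
    - 50.0
    - 65.0
    - 80.0
    - 95.0
    - 100.0
    interpolation: linear
  class_standards:
    I: 7.5
    II: 6.0
    III: 5.0
    IV: 3.0
    V: 2.0
  direction: below
  mdl: 0.1
TN:
  unit: mg/L
  weight: 2.0
  curve:
    conc:
    - 0.0
    - 0.2
    - 0.5
    - 1.0
    - 1.5
    - 2.0
    - 3.0
    - 4.8
    ci:
    - 100.0
    - 95.0
    - 85.0
    - 65.0
    - 45.0
    - 30.0
    - 10.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 0.2
    II: 0.5
    III: 1.0
    IV: 1.5
    V: 2.0
  direction: above
  mdl: 0.05
NH3_N:
  unit: mg/L
  weight: 3.0
  curve:
    conc:
    - 0.0
    - 0.15
    - 0.5
    - 1.0
    - 1.5
    - 2.0
    - 3.0
    - 5.0
    ci:
    - 100.0
    - 95.0
    - 85.0
    - 65.0
    - 45.0
    - 30.0
    - 10.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 0.15
    II: 0.5
    III: 1.0
    IV: 1.5
    V: 2.0
  direction: above
  mdl: 0.025
NO3_N:
  unit: mg/L
  weight: 2.0
  curve:
    conc:
    - 0.0
    - 1.0
    - 2.0
    - 5.0
    - 10.0
    - 20.0
    - 50.0
    ci:
    - 100.0
    - 95.0
    - 90.0
    - 75.0
    - 50.0
    - 20.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 10.0
    II: 10.0
    III: 10.0
    IV: 10.0
    V: 10.0
  direction: above
  mdl: 0.08
TP:
  unit: mg/L
  weight: 2.0
  curve:
    conc:
    - 0.0
    - 0.02
    - 0.1
    - 0.2
    - 0.3
    - 0.4
    - 0.6
    - 1.0
    ci:
    - 100.0
    - 95.0
    - 85.0
    - 65.0
    - 45.0
    - 30.0
    - 10.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 0.02
    II: 0.1
    III: 0.2
    IV: 0.3
    V: 0.4
  direction: above
  mdl: 0.01
CODMn:
  unit: mg/L
  weight: 3.0
  curve:
    conc:
    - 0.0
    - 2.0
    - 4.0
    - 6.0
    - 10.0
    - 15.0
    - 25.0
    ci:
    - 100.0
    - 95.0
    - 80.0
    - 60.0
    - 30.0
    - 10.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 2.0
    II: 4.0
    III: 6.0
    IV: 10.0
    V: 15.0
  direction: above
  mdl: 0.5
Cl:
  unit: mg/L
  weight: 1.0
  curve:
    conc:
    - 0.0
    - 50.0
    - 100.0
    - 150.0
    - 250.0
    - 400.0
    - 700.0
    ci:
    - 100.0
    - 90.0
    - 75.0
    - 60.0
    - 40.0
    - 15.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 250.0
    II: 250.0
    III: 250.0
    IV: 250.0
    V: 250.0
  direction: above
  mdl: 1.0
SO4:
  unit: mg/L
  weight: 1.0
  curve:
    conc:
    - 0.0
    - 50.0
    - 100.0
    - 150.0
    - 250.0
    - 400.0
    - 700.0
    ci:
    - 100.0
    - 90.0
    - 75.0
    - 60.0
    - 40.0
    - 15.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 250.0
    II: 250.0
    III: 250.0
    IV: 250.0
    V: 250.0
  direction: above
  mdl: 2.0
F_coli:
  unit: colonies/L
  weight: 3.0
  curve:
    conc:
    - 0.0
    - 200.0
    - 2000.0
    - 10000.0
    - 20000.0
    - 40000.0
    - 100000.0
    ci:
    - 100.0
    - 90.0
    - 70.0
    - 50.0
    - 30.0
    - 10.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 200.0
    II: 2000.0
    III: 10000.0
    IV: 20000.0
    V: 40000.0
  direction: above
  mdl: 20.0
Fe:
  unit: mg/L
  weight: 3.0
  curve:
    conc:
    - 0.0
    - 0.1
    - 0.3
    - 0.6
    - 1.0
    - 2.0
    - 4.0
    ci:
    - 100.0
    - 95.0
    - 80.0
    - 55.0
    - 35.0
    - 10.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 0.3
    II: 0.3
    III: 0.3
    IV: 0.3
    V: 0.3
  direction: above
  mdl: 0.03
Mn:
  unit: mg/L
  weight: 3.0
  curve:
    conc:
    - 0.0
    - 0.05
    - 0.1
    - 0.3
    - 0.5
    - 1.0
    - 2.0
    ci:
    - 100.0
    - 95.0
    - 80.0
    - 55.0
    - 35.0
    - 10.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 0.1
    II: 0.1
    III: 0.1
    IV: 0.1
    V: 0.1
  direction: above
  mdl: 0.01
F_ion:
  unit: mg/L
  weight: 1.0
  curve:
    conc:
    - 0.0
    - 0.5
    - 1.0
    - 1.5
    - 2.0
    - 3.0
    - 5.0
    ci:
    - 100.0
    - 95.0
    - 80.0
    - 55.0
    - 35.0
    - 10.0
    - 0.0
    interpolation: linear
  class_standards:
    I: 1.0
    II: 1.0
    III: 1.0
    IV: 1.5
    V: 1.5
  direction: above
  mdl: 0.02
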