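feature_order:
- age_at_diagnosis
- bmi
- hba1c
- homa2_b
- homa2_ir
labels:
- SIDD
- SIRD
- MOD
- MARD
scaling:
  center:
  - 38.83
  - 32.96
  - 69.28
  - 84.11
  - 3.21
  scale:
  - 5.96
  - 6.92
  - 25.88
  - 48.91
  - 1.58
  transform:
  - none
  - none
  - none
  - none
  - none
centroids:
  SIDD:
  - 0.0251678
  - -0.6748555
  - 1.2102009
  - -0.8808015
  - -0.3417722
  SIRD:
  - 0.1862416
  - 0.5289017
  - -0.5444359
  - 2.3271315
  - 1.8734177
  MOD:
  - -0.045302
  - 0.283237
  - -0.4022411
  - 0.2183603
  - 0.0632911
  MARD:
  - 0.6157718
  - -1.2789017
  - -0.9053323
  - -0.080965
  - -0.9050633
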