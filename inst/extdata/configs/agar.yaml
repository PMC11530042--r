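scenario: agar
geometry:
  domain_mm: 90.0
  dx_mm: 1.0
  square_mm: 30.0
  thickness_mm: 4.0
transport:
  D_agar:
    value: 0.72
    unit: mm2/h
clearance:
  half_life: disabled
source:
  type: peppas
  k: 0.0423164
  'n': 0.5
  t_end: 504.0
  n_points: 211.0
  areal_load_ug_mm2: 100.0
thresholds:
  MIC: 2.0
  toxicity: 1000.0
run:
  t_end: 24.0
  record_every: 6.0
  seed: 1.0
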