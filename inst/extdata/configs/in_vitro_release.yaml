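scenario: in_vitro_release
geometry:
  slab_length_mm: 20.8
  dx_mm: 0.4
  cross_section_mm2: 1.0
transport:
  D_water:
    value: 2.83e-06
    unit: cm2/s
clearance:
  half_life: disabled
source:
  initial_concentration: 1000.0
thresholds:
  MIC: 2.0
  toxicity: 1000.0
run:
  t_end: 480.0
  record_every: 12.0
  seed: 1.0
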