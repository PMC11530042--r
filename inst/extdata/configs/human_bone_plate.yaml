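scenario: human_bone_plate
geometry:
  tissue_mm: 3.0
  tissue_dx_mm: 0.1
  cortical_mm: 3.5
  cancellous_mm: 14.0
  bone_dx_mm: 0.5
  cross_section_mm2: 1.0
  height_mm: 10.0
transport:
  tissue_D:
    value: 2.08e-06
    unit: cm2/s
  bone:
    cortical:
      D0: 2.83e-06
      delta: 0.84
      phi: 0.05
      tau: 1.1
      D_scale: 1.0
    cancellous:
      D0: 2.83e-06
      delta: 0.96
      phi: 0.95
      tau: 1.1
      D_scale: 1.0
clearance:
  half_life: 4.0
  mode: increment
source:
  type: peppas
  k: 0.0423164
  'n': 0.5
  t_end: 504.0
  n_points: 211.0
  total_load: 100.0
  coating_area: 1.0
  tissue_split: 0.5
thresholds:
  MIC: 2.0
  toxicity: 1000.0
run:
  t_end: 24.0
  record_every: 0.5
  seed: 1.0
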