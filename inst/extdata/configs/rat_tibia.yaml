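scenario: rat_tibia
geometry:
  cortical_mm: 0.7
  cancellous_mm: 1.6
  dx_mm: 0.1
  cross_section_mm2: 1.0
transport:
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
  dose_ug: 1.0
thresholds:
  MIC: 2.0
  toxicity: 1000.0
run:
  t_end: 24.0
  record_every: 0.25
  seed: 1.0
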