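# Synthetic torso scenario presets (parameters of torso_spec(); mm / degrees).
# These are plausible deformity phenotypes for exercising the pipeline,
# not reconstructions of any scanned individual.

healthy:
  base_a: 170
  base_b: 120
  superellipse_exponent: 2.5
  dip_depth: 10
  dip_width: 12
  dip_angle: 0
  hump_amplitude: 0

thoracic_t8:
  base_a: 170
  base_b: 120
  superellipse_exponent: 2.5
  dip_depth: 12
  dip_width: 12
  dip_angle: 0
  hump_amplitude: 18
  hump_angle: 50
  hump_width: 25
  apex_level: T8
  apex_spread: 2

double_curve:
  base_a: 170
  base_b: 120
  superellipse_exponent: 2.5
  dip_depth: 12
  dip_width: 12
  dip_angle: 0
  hump_amplitude: [16, 12]
  hump_angle: [50, -55]
  hump_width: [25, 20]
  apex_level: [T9, L2]
  apex_spread: [1.5, 1.5]
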