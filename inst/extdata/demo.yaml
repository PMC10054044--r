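# Demo configuration: micropillars at bench conditions, 2 s acquisition.
# Unset keys fall back to the documented defaults.
seed: 1
flow:
  qj_ul_h: 1
  qs_ul_h: 1
  velocity_model: mean_channel
simulation:
  mode: single
  population: micropillar
  concentration_per_ml: 3.0e+7
  duration_s: 2
  gain: medium
analysis:
  boundary_um: 2
output:
  write_trace: false
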