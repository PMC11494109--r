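# Minimal pipeline configuration: overrides merge over default_run_config().
seed: 7
flow:
  flow_rate: 18
  viscosity: 1.0
geometry:
  width: 200
  inlet_height: 50
  occlusion_fraction: 0.8
stats:
  alpha: 0.05
  correction: holm-sidak
  marker: eplus
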