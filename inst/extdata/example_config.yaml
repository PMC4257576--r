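# Example configuration: overrides a few defaults, everything else is
# filled in by load_config().
eco:
  a_min: 2.2     # relax the resistance cost into the cycling regime
  q: 1
costs:
  c_h: 1.3
  c_p: 0.7
kernel:
  s_k: 0.11
numerics:
  n_events: 400
  speeds: [1.0, 0.5]
synthetic:
  regime: mixed
  seed: 7
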