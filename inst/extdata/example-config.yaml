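# Example scenario configuration. Unset keys fall back to the published
# defaults (see ?scenario_config); lengths in mm, forces in N.
scenario: baseline-rigid
domain:
  gap_width: 0.7
  cortex_thickness: 0.2
  marrow_width: 1.0
  domain_width: 1.9
  domain_height: 1.9
  callus_radius: 0.9
  pitch: 0.01
ec:
  p1: 0.4
  p2: 0.4
  p3: 0.2
ovsc:
  seed_frac: 0.2
replicates: 6
seed: 1
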