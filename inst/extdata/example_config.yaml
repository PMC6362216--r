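# Run configuration mirroring run_config(); absent keys keep their defaults.
species_identity_threshold: 98.7
otu_identity_threshold: 99.0
screen_min_identity: 95.0
screen_min_length: 300
majority_fraction: 0.5
random_seed: 1
region_windows:
  - {name: V1V2, start: 8, end: 338}
  - {name: V4V6, start: 515, end: 1064}
  - {name: V7V8, start: 1115, end: 1392}
chimera:
  scan_step: 10
  end_margin: 100
  delta_support: 1.0
  delta_conflict: 3.0
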