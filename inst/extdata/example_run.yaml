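# Desk-scale example configuration for run_pipeline()
seed: 42
output_dir: ecdyn_report
construct:
  kind: dimer
  arrangement: HT2
  separation: 14
plan:
  blocks:
    - {chain: A, from: 1,  to: 60}
    - {chain: A, from: 75, to: 140}
    - {chain: B, from: 1,  to: 60}
    - {chain: B, from: 75, to: 140}
  couplings:
    - {chain_a: A, from_a: 61, to_a: 95, chain_b: B, from_b: 61, to_b: 95, k: 400}
  k_block: 2000
  k_linker: 40
simulation:
  n_frames: 4000        # 400 ps at 0.1 ps spacing
  frame_interval: 0.1
  satellites: false     # C-alpha sites only; set true for heavy-atom PCA
analysis:
  selection: calpha
  k_max: 20
  window: 200           # ps per segment
  take_last: 400        # trailing analysis window, ps
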