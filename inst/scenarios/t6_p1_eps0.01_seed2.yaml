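name: t6_p1_eps0.01_seed2
system:
  kind: model
  M_sys: 8
  electrons: 4
target:
  p: 1
  kind: mixture
  occ1:
  - 1a
  - 1b
  - 2a
  - 2b
  occ2:
  - 1a
  - 1b
  - 3a
  - 2b
  w: 0.5
  noise:
    eps: 0.01
    seed: 2
algorithms:
- ensemble
settings:
  delta: 3.0e-05
  zero_threshold: 3.0e-05
pool:
  conserve_register_number: yes
  conserve_sz: none
  distinct_spatial_only: no
  dedupe: yes
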