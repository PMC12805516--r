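name: t3_4e3o_w00
system:
  kind: model
  M_sys: 6
  electrons: 4
target:
  p: 2
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
  - 3b
  w: 0.0
  noise: ~
algorithms:
- pure
- ensemble
settings:
  delta: 5.0e-09
  zero_threshold: 1.0e-08
pool:
  conserve_register_number: yes
  conserve_sz: none
  distinct_spatial_only: no
  dedupe: yes
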