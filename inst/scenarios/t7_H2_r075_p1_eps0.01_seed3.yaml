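name: t7_H2_r075_p1_eps0.01_seed3
system:
  kind: molecule
  atoms: 2
  spacing: 0.75
  electrons: 2
target:
  p: 1
  kind: thermal
  noise:
    eps: 0.01
    seed: 3
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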