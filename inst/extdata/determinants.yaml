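sys_4e3o:
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
  M_sys: 6
sub1:
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
  M_sys: 8
sub2:
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
  M_sys: 8
sub3:
  occ1:
  - 1a
  - 1b
  - 2a
  - 2b
  occ2:
  - 1a
  - 3b
  - 4a
  - 4b
  M_sys: 8
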