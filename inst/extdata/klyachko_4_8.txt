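kind b a1 a2 a3 a4 a5 a6 a7 a8
pauli 1 1 0 0 0 0 0 0 0
gpc 0 0 0 0 0 1 -1 -1 -1
gpc 0 0 0 1 -1 0 0 -1 -1
gpc 0 0 1 0 -1 0 -1 0 -1
gpc 0 1 -1 0 0 0 0 -1 -1
gpc 0 1 0 -1 0 0 -1 0 -1
gpc 0 1 0 0 -1 -1 0 0 -1
gpc 0 1 0 0 -1 0 -1 -1 0
gpc 2 0 1 1 0 1 0 0 -1
gpc 2 1 0 0 1 1 0 0 -1
gpc 2 1 0 1 0 0 1 0 -1
gpc 2 1 0 1 0 1 0 -1 0
gpc 2 1 1 0 0 0 0 1 -1
gpc 2 1 1 0 0 1 -1 0 0
gpc 2 1 1 1 -1 0 0 0 0
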