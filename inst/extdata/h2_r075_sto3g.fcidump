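 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
  6.7284794694402961E-01   1   1   1   1
  1.8177153657866843E-01   2   1   2   1
  6.6197725947497110E-01   2   2   1   1
  6.9581515105532787E-01   2   2   2   2
 -1.2472845052091595E+00   1   1   0   0
 -4.8127293111075392E-01   2   2   0   0
  7.0556961453733325E-01   0   0   0   0
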