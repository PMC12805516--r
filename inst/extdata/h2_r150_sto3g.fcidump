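 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
  5.5270338305689148E-01   1   1   1   1
  2.2953593606280795E-01   2   1   2   1
  5.5968415560817486E-01   2   2   1   1
  5.8342076119804442E-01   2   2   2   2
 -9.0818087245276047E-01   1   1   0   0
 -6.6533693576747766E-01   2   2   0   0
  3.5278480726866662E-01   0   0   0   0
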