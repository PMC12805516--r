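 &FCI NORB=3,NELEC=3,MS2=0,
  ORBSYM=1,1,1,
  ISYM=1,
 &END
  6.7237072056999725E-01   1   1   1   1
  1.2308032745764685E-01   2   1   2   1
  5.4416204131658008E-01   2   2   1   1
  5.8342076119804309E-01   2   2   2   2
  1.2748732118115830E-01   3   1   1   1
 -1.2067345274332258E-02   3   1   2   2
  1.2363387081687061E-01   3   1   3   1
 -1.3104108555389088E-01   3   2   2   1
  1.7474188836295318E-01   3   2   3   2
  6.3604307979156938E-01   3   3   1   1
  5.8310799972606819E-01   3   3   2   2
  7.9193065476866359E-02   3   3   3   1
  6.6632383936502637E-01   3   3   3   3
 -1.8038332509943826E+00   1   1   0   0
 -1.2568698342476559E+00   2   2   0   0
 -5.2223993447837713E-01   3   3   0   0
  1.7639240363433331E+00   0   0   0   0
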