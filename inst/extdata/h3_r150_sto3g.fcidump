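 &FCI NORB=3,NELEC=3,MS2=0,
  ORBSYM=1,1,1,
  ISYM=1,
 &END
  5.8213685783667068E-01   1   1   1   1
  8.6381193214158256E-02   2   1   2   1
  3.7157766897708594E-01   2   2   1   1
  4.7992981750081942E-01   2   2   2   2
  1.3908127585584107E-01   3   1   1   1
 -5.9609231624832497E-02   3   1   2   2
  1.2658275331410040E-01   3   1   3   1
 -1.3511204534647664E-01   3   2   2   1
  2.2879022726034406E-01   3   2   3   2
  4.5928943792217169E-01   3   3   1   1
  4.5261108017206120E-01   3   3   2   2
  1.6531092425538199E-02   3   3   3   1
  4.7396633108408154E-01   3   3   3   3
 -1.2182675464654289E+00   1   1   0   0
 -9.7979079849724704E-01   2   2   0   0
 -8.3702276003182152E-01   3   3   0   0
  8.8196201817166653E-01   0   0   0   0
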