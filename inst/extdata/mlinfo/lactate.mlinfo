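# L-lactate HSQC entry (shifts in ppm, couplings in Hz)
metabolite:
  name: lactate
  n_carbons: 3

carbons:
  # index  h_ppm  c_ppm   ("-" = unprotonated / unobservable)
  1  -     -
  2  4.10  69.33
  3  1.31  20.91

jcc:
  1 2 54.9
  2 3 37.1
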