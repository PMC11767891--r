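# L-alanine HSQC entry
metabolite:
  name: alanine
  n_carbons: 3

carbons:
  1  -     -
  2  3.77  51.15
  3  1.47  16.99

jcc:
  1 2 53.8
  2 3 35.1
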