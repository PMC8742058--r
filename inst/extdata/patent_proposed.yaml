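core: CC{R1}
rules:
  R1:
  - CO
  - OC
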