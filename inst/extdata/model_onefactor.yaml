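# one factor, five indicators
factors:
  F1: [x1, x2, x3, x4, x5]
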