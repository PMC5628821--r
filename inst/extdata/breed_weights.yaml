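weights:
  Mediterranean: 0.3
  Murrah: 0.3
  Jaffarabadi: 0.2
  NiliRavi: 0.2
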