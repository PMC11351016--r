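{
  "iptm": 0.84,
  "ptm": 0.91
}
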