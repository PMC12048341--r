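{
  "0": "no record",
  "1": "measles vaccine / dose 1",
  "2": "measles vaccine / dose 2",
  "10": "polio vaccine / dose 1",
  "11": "polio vaccine / dose 2",
  "42": "mRNA vaccine / dose 2 / 2026-Q1",
  "127": "test pattern"
}
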