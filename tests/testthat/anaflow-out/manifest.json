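{
  "subcommand": "nonsense",
  "options": [],
  "package": "0.9.0",
  "r_version": "R version 4.3.3 (2024-02-29)",
  "timestamp": "2026-09-24T10:41:23"
}
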