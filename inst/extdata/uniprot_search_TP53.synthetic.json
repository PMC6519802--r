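{
  "results": [
    { "primaryAccession": "P04637", "genes": [ { "geneName": { "value": "TP53" } } ] }
  ]
}
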