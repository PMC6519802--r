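{
  "primaryAccession": "P04637",
  "organism": { "taxonId": 9606, "scientificName": "Homo sapiens" },
  "genes": [ { "geneName": { "value": "TP53" } } ],
  "sequence": { "length": 393 },
  "features": [
    {
      "type": "Domain",
      "description": "P53_TAD",
      "location": { "start": { "value": 6 }, "end": { "value": 29 } }
    },
    {
      "type": "Domain",
      "description": "P53",
      "location": { "start": { "value": 95 }, "end": { "value": 288 } }
    },
    {
      "type": "Domain",
      "description": "P53_tetramer",
      "location": { "start": { "value": 318 }, "end": { "value": 358 } }
    },
    {
      "type": "Region",
      "description": "Interaction with DNA",
      "location": { "start": { "value": 273 }, "end": { "value": 280 } }
    }
  ]
}
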