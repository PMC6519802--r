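accession: P04637
gene: TP53
taxon: 9606
length: 393
domain	P53_TAD	6	29
domain	P53	95	288
domain	P53_tetramer	318	358
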