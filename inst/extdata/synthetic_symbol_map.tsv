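symbol	gene_id
Ctss	G000001
Stat1	G000002
Ptgs1	G000003
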