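target	affinity_kcal_mol
CTSS	-8.77
STAT1	-7.59
PTGS1	-6.62
TOP2A	-6.00
PSMB9	-5.34
CDK1	-4.97
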