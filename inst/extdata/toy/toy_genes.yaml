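name: sensory ataxia toy set
taxon: Homo sapiens
genes:
  - EGR2
  - MPZ
  - PMP22
  - PRX
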