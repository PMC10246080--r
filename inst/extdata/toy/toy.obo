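format-version: 1.4

[Term]
id: FX:0000001
name: cell signaling

[Term]
id: FX:0000002
name: myelination
synonym: "myelinogenesis" EXACT []
is_a: FX:0000001

[Term]
id: FX:0000003
name: Schwann cell differentiation
is_a: FX:0000001

[Term]
id: FX:0000004
name: axon ensheathment
is_a: FX:0000002

[Term]
id: FX:0000005
name: glucose metabolism
relationship: part_of FX:0000001

[Term]
id: FX:0000006
name: myelin upkeep
synonym: "myelin renewal" EXACT []
is_obsolete: true
replaced_by: FX:0000002
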