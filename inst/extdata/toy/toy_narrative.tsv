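EGR2	Transcription factor required for myelination of peripheral nerves.
MPZ	Structural myelin protein involved in myelination of Schwann cells.
PMP22	Membrane component involved in axon ensheathment and myelin stability.
PRX	Scaffolding protein involved in axon ensheathment.
SOX10	Regulator of Schwann cell differentiation.
GPI	Enzyme of glucose metabolism.
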