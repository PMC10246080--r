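!gaf-version: 2.2
GSX	EGR2	EGR2		FX:0000002	GSX:0000001	IEA		P	EGR2		gene	taxon:9606	20260101	GSX
GSX	MPZ	MPZ		FX:0000002	GSX:0000001	IEA		P	MPZ		gene	taxon:9606	20260101	GSX
GSX	PMP22	PMP22		FX:0000004	GSX:0000001	IEA		P	PMP22		gene	taxon:9606	20260101	GSX
GSX	PRX	PRX		FX:0000004	GSX:0000001	IEA		P	PRX		gene	taxon:9606	20260101	GSX
GSX	SOX10	SOX10		FX:0000003	GSX:0000001	IEA		P	SOX10		gene	taxon:9606	20260101	GSX
GSX	GPI	GPI		FX:0000005	GSX:0000001	IEA		P	GPI		gene	taxon:9606	20260101	GSX
GSX	GPI	GPI	NOT	FX:0000002	GSX:0000001	IEA		P	GPI		gene	taxon:9606	20260101	GSX
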