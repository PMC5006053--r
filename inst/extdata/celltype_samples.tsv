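sample_id	cell_type	replicate
RGC_1	RGC	1
RGC_2	RGC	2
CorticalNeuron_1	CorticalNeuron	1
CorticalNeuron_2	CorticalNeuron	2
Astrocyte_1	Astrocyte	1
Astrocyte_2	Astrocyte	2
Oligodendrocyte_1	Oligodendrocyte	1
Oligodendrocyte_2	Oligodendrocyte	2
Microglia_1	Microglia	1
Microglia_2	Microglia	2
Endothelial_1	Endothelial	1
Endothelial_2	Endothelial	2
ECP_1	ECP	1
ECP_2	ECP	2
MEP_1	MEP	1
MEP_2	MEP	2
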