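sample_id	RGC_1	RGC_2	CorticalNeuron_1	CorticalNeuron_2	Astrocyte_1	Astrocyte_2	Oligodendrocyte_1	Oligodendrocyte_2	Microglia_1	Microglia_2	Endothelial_1	Endothelial_2	ECP_1	ECP_2	MEP_1	MEP_2
RGC_1	1	0.98	0.41	0.7	0.4	0.39	0.52	0.49	0.14	0.11	0.49	0.51	0.25	0.25	0.27	0.27
RGC_2	0.98	1	0.46	0.75	0.42	0.41	0.57	0.57	0.14	0.11	0.53	0.52	0.3	0.26	0.28	0.34
CorticalNeuron_1	0.41	0.46	1	0.88	0.43	0.36	0.51	0.64	0.15	0.14	0.58	0.46	0.26	0.22	0.21	0.41
CorticalNeuron_2	0.7	0.75	0.88	1	0.56	0.5	0.64	0.73	0.22	0.2	0.69	0.62	0.36	0.32	0.31	0.48
Astrocyte_1	0.4	0.42	0.43	0.56	1	0.98	0.39	0.43	0.46	0.43	0.41	0.37	0.19	0.17	0.2	0.26
Astrocyte_2	0.39	0.41	0.36	0.5	0.98	1	0.34	0.36	0.46	0.43	0.38	0.36	0.18	0.17	0.2	0.24
Oligodendrocyte_1	0.52	0.57	0.51	0.64	0.39	0.34	1	0.97	0.15	0.12	0.55	0.53	0.26	0.23	0.21	0.31
Oligodendrocyte_2	0.49	0.57	0.64	0.73	0.43	0.36	0.97	1	0.17	0.14	0.59	0.53	0.29	0.23	0.21	0.38
Microglia_1	0.14	0.14	0.15	0.22	0.46	0.46	0.15	0.17	1	0.99	0.28	0.28	0.16	0.18	0.19	0.19
Microglia_2	0.11	0.11	0.14	0.2	0.43	0.43	0.12	0.14	0.99	1	0.23	0.24	0.15	0.17	0.18	0.18
Endothelial_1	0.49	0.53	0.58	0.69	0.41	0.38	0.55	0.59	0.28	0.23	1	0.98	0.4	0.4	0.4	0.48
Endothelial_2	0.51	0.52	0.46	0.62	0.37	0.36	0.53	0.53	0.28	0.24	0.98	1	0.38	0.41	0.41	0.43
ECP_1	0.25	0.3	0.26	0.36	0.19	0.18	0.26	0.29	0.16	0.15	0.4	0.38	1	0.93	0.85	0.9
ECP_2	0.25	0.26	0.22	0.32	0.17	0.17	0.23	0.23	0.18	0.17	0.4	0.41	0.93	1	0.88	0.82
MEP_1	0.27	0.28	0.21	0.31	0.2	0.2	0.21	0.21	0.19	0.18	0.4	0.41	0.85	0.88	1	0.88
MEP_2	0.27	0.34	0.41	0.48	0.26	0.24	0.31	0.38	0.19	0.18	0.48	0.43	0.9	0.82	0.88	1
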