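specimen_id	species	latitude	longitude	is_reference	coverage	mapped_noncoding_pct	mapped_coding_pct	het_pct	het_coding_pct
NVG-3306	C_cecrops	31.524582	-93.098485	TRUE	78	100.0	99.9	1.16	0.56
NVG-3307	C_cecrops	31.524582	-93.098485	FALSE	14.1	88.7	97.6	1.46	0.64
NVG-3515	C_cecrops	30.50644	-95.08783	FALSE	12.6	88.2	97.7	1.44	0.65
NVG-3348	C_isobeon	26.05681	-97.84284	FALSE	16.5	84.4	97.8	1.79	0.82
NVG-3431	C_isobeon	26.22615	-98.43653	FALSE	14.5	84.2	97.7	1.83	0.84
NVG-3978	C_isobeon	32.85531	-96.71484	FALSE	14.1	83.1	97.4	1.58	0.71
NVG-4166	C_isobeon	29.72914	-93.87508	FALSE	13.0	83.2	97.4	1.59	0.71
NVG-3033	C_isobeon	9.8833	-84.0333	FALSE	13.0	82.5	96.0	1.96	1.04
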