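rsid	effect_allele	other_allele	eaf	beta	se	pvalue	n
rs3755967	T	C	0.28	-0.265	0.012	1e-100	79366
rs12785878	T	G	0.75	0.110	0.011	2e-23	79366
rs10741657	A	G	0.40	0.088	0.010	1e-18	79366
rs17216707	T	C	0.79	0.075	0.012	4e-10	79366
rs117913124	A	G	0.026	-0.230	0.030	2e-14	42274
rs8018720	G	T	0.18	-0.058	0.011	6e-9	79366
rs10745742	T	C	0.40	0.064	0.009	8e-13	79366
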