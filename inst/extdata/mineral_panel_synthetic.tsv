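rsid	effect_allele	other_allele	eaf	beta	se	pval	n
rs4072037	A	G	0.46	0.023	0.004	1.2e-09	23829
rs7965584	A	G	0.68	0.021	0.004	3.4e-09	23829
rs3925584	T	C	0.55	0.019	0.004	4.1e-08	23829
rs448378	A	G	0.51	0.017	0.003	2.2e-08	23829
rs13146355	A	G	0.43	0.018	0.003	1.9e-08	23829
rs11144134	C	T	0.09	0.039	0.007	8.1e-09	23829
rs1801725	T	G	0.15	0.071	0.006	5.5e-40	61079
rs1550532	C	G	0.31	0.022	0.004	7.1e-09	61079
rs7481584	G	A	0.72	0.021	0.004	1.1e-08	61079
rs1570669	G	A	0.34	0.023	0.004	9.1e-10	61079
rs7336933	G	A	0.81	0.025	0.005	4.3e-08	61079
rs780094	C	T	0.61	0.022	0.004	1.9e-08	61079
rs10491003	T	C	0.09	0.034	0.006	3.3e-08	61079
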