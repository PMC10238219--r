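feature	target
gene0001	1
gene0002	1
gene0003	1
gene0004	1
gene0005	1
gene0006	1
gene0007	2
gene0008	2
gene0009	2
gene0010	2
gene0011	2
gene0012	2
gene0013	3
gene0014	3
gene0015	3
gene0016	3
gene0017	3
gene0018	3
gene0019	0
gene0020	0
gene0021	0
gene0022	0
gene0023	0
gene0024	0
gene0025	0
gene0026	0
gene0027	0
gene0028	0
gene0029	0
gene0030	0
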