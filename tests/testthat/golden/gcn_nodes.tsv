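node	kind	subnetwork	degree	local_cc
gene0003	gene	0	3	1
gene0001	gene	0	3	1
gene0004	gene	0	5	0.7
gene0007	gene	2	4	1
gene0008	gene	2	5	0.9
gene0010	gene	2	5	0.9
gene0002	gene	1	2	1
gene0005	gene	0	4	0.833333333333333
gene0006	gene	0	3	1
gene0011	gene	1	2	1
gene0012	gene	2	4	1
gene0015	gene	1	1	0
gene0018	gene	1	2	1
gene0028	gene	1	1	0
pheno_pos	phenotype	1	15	0.2
pheno_neg	phenotype	0	13	0.269230769230769
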