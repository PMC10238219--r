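node	kind	subnetwork	degree	local_cc
met002	metabolite	0	7	0.571428571428571
met003	metabolite	1	7	0.571428571428571
met004	metabolite	1	4	1
met005	metabolite	1	4	1
met007	metabolite	0	4	1
met008	metabolite	0	4	1
met006	metabolite	1	4	1
met009	metabolite	0	4	1
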