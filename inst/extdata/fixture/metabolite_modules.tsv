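feature	target
met001	1
met002	1
met003	1
met004	2
met005	2
met006	2
met007	3
met008	3
met009	3
met010	0
met011	0
met012	0
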