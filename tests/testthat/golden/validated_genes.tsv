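feature
gene0001
gene0002
gene0003
gene0004
gene0006
gene0010
gene0015
gene0016
gene0018
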