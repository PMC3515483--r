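item	weight
81	0.8
82	1
83	0.8
84	1.6
85	1
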