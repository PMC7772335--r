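2R	0	1000000	0.8
2R	1000000	2000000	2.1
2R	2000000	3000000	4.6
3L	0	1500000	1.2
3L	1500000	3000000	3.4
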