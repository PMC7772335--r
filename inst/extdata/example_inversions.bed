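2R	1200000	1800000
3L	200000	900000
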