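# Global duplex parameters: intermolecular initiation, Ninio-style asymmetry, default max loop size per side.
key	value
duplex_init	4.09
asym_coef	0.6
asym_max	3
max_loop	15
version	1
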