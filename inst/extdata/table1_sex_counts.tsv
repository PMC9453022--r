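group	male	female
MCI	48	3
nMCI	47	1
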