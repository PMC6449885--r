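mirna	disease
A	dA
B	dA
B	dB
C	dB
D	dR
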