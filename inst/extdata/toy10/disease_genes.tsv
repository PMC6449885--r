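disease	gene
dA	h1
dA	h2
dB	h2
dR	h3
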