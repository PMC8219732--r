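# mutually exclusive neurotransmitter classes per presynaptic neuron
attribute: type
exclusive: GABA, glycine
exclusive: glutamate, acetylcholine
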