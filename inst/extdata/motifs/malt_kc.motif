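# author: motifquery examples
# comment: antennal-lobe-tract input to a Kenyon cell with a strong synapse
A -> B [weight >= 10]
A.type = "mALT"
B.type = "KC"
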