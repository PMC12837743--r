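>SYN0001 SOXlike_synthetic
A [ 94 95 2 90 93 1 ]
C [ 2 1 94 4 2 2 ]
G [ 2 2 2 3 3 2 ]
T [ 2 2 2 3 2 95 ]
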