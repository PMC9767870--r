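>AP1
A [ 0 0 97 0 0 97 0 ]
C [ 0 0 0 97 0 0 0 ]
G [ 0 97 0 0 0 0 0 ]
T [ 97 0 0 0 97 0 97 ]
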