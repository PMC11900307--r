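node1	node2
P1	P2
P2	P3
P3	P4
P4	P5
P1	P3
P2	P5
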