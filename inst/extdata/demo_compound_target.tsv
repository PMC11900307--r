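compound	target
C1	P1
C1	P2
C2	P2
C2	P3
C3	P1
C4	P4
C5	P5
C6	P4
C6	P5
C7	P3
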