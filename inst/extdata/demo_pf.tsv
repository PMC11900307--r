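protein	function
P1	F1
P2	F1
P3	F2
P5	F2
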