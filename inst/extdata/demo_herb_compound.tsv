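herb	compound
HerbA	C1
HerbA	C2
HerbA	C3
HerbB	C4
HerbB	C5
HerbB	C6
HerbC	C7
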