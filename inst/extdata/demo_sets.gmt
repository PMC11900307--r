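SET1	membrane signaling	P1	P2	P3
SET2	stress response	P4	P5
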