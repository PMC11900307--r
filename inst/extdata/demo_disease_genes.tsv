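gene	source	association_type
P1	curated	genetic
P2	curated	genetic
P3	model	animal_model
P5	curated	therapeutic
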