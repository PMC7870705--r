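plant_id	M1	M2	M3	M4	M5	M6	M7	M8	phenotype
9-7	T	T	T	T	H	H	H	H	SS
23-2	H	H	H	H	H	T	T	T	SS
28-1	H	H	H	H	H	H	H	H	SS
38-3	T	T	T	-	H	H	H	H	SS
39-7	H	H	H	H	T	T	T	T	N
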