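population	n_TT	n_TG	n_GG
S22A_j1	54	57	17
S22A_j2	19	20	0
S22A_j3	46	55	2
Empty_vector	35	41	0
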