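population	n_TT	n_TG	n_GG
Eco72I	13	20	0
XmnI_a	26	21	5
SalI	18	41	19
XmnI_b	15	12	2
Non-transgenic	42	43	5
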