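marker	bp	cm
M1	10000	0.0
M2	42000	0.8
M3	78000	1.6
M4	104000	2.4
M5	131000	3.2
M6	166000	4.0
M7	198000	4.8
M8	225000	5.6
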