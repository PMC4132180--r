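family	line	zz	total	balancer
140	1	0	110	FALSE
140	2	3	90	FALSE
140	3	0	56	FALSE
140	5	29	112	FALSE
140	6	2	72	FALSE
140	9	3	127	FALSE
140	11	0	120	FALSE
140	12	1	64	FALSE
140	14	1	101	FALSE
140	15	0	70	FALSE
140	16	2	63	FALSE
140	18	3	71	FALSE
140	19	1	54	FALSE
140	24	2	103	FALSE
140	28	0	62	FALSE
140	29	1	125	FALSE
140	30	1	118	FALSE
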