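zotu	AS_HF_1	AS_HF_2	AS_CK_1	AS_CK_2
Zotu1	5200	4800	400	500
Zotu2	3600	3900	5200	5400
Zotu3	340	310	200	180
Zotu4	25	30	150	160
Zotu5	5	4	40	35
Zotu6	2	1	20	25
Zotu7	900	950	100	120
Zotu8	300	280	400	380
Zotu9	80	90	300	290
Zotu10	60	55	250	260
Zotu11	150	160	60	70
Zotu12	30	25	110	100
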