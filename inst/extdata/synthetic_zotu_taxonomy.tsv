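zotu	gene	clade	genus
Zotu1	AOA	NS-Gamma	uncultured_Nitrososphaerales
Zotu2	AOA	NS-Alpha	Nitrososphaera
Zotu3	AOA	NS-Zeta	Nitrosocosmicus
Zotu4	AOA	NT-Alpha	Nitrosotalea
Zotu5	AOA	NS-Beta	Nitrososphaera
Zotu6	AOA	NS-Delta	Nitrososphaera
Zotu7	AOB	Nitrosospira	Nitrosospira
Zotu8	AOB	Nitrosospira	Nitrosospira
Zotu9	ComA	ComA.2.1	Nitrospira
Zotu10	ComA	ComA.2.2	Nitrospira
Zotu11	AOB	Nitrosospira	Nitrosospira
Zotu12	ComA	ComA.2.2	Nitrospira
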