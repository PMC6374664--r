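species_a	species_b	alpha_drift	alpha_postdrift
BUR	BSD	0.3	0.14
CMM	BSD	0.11	0.19
CMM	BUR	0.31	0.31
CMS	BSD	0.04	0.22
CMS	BUR	0.19	0.14
CMS	CMM	0.48	0.19
CRC	BSD	0.27	0.23
CRC	BUR	0.41	0.49
CRC	CMM	0.16	0.2
CRC	CMS	0.23	0.2
HHC	BSD	0.25	0.36
HHC	BUR	0.53	0.35
HHC	CMM	0.36	0.5
HHC	CMS	0.19	0.24
HHC	CRC	0.44	0.49
LOP	BSD	0.24	0.36
LOP	BUR	0.46	0.27
LOP	CMM	0.18	0.24
LOP	CMS	0.05	0.16
LOP	CRC	0.26	0.24
LOP	HHC	0.38	0.38
PUS	BSD	0.17	0.12
PUS	BUR	0.1	0.09
PUS	CMM	0.28	0.2
PUS	CMS	0.01	0.07
PUS	CRC	0.11	0.1
PUS	HHC	0.27	0.1
PUS	LOP	0.1	0.23
RAD	BSD	0.37	0.42
RAD	BUR	0.51	0.23
RAD	CMM	0.23	0.26
RAD	CMS	0.06	0.37
RAD	CRC	0.29	0.23
RAD	HHC	0.44	0.25
RAD	LOP	0.79	0.36
RAD	PUS	0.23	0.26
ROB	BSD	0.33	0.15
ROB	BUR	0.55	0.33
ROB	CMM	0.3	0.15
ROB	CMS	0.05	0.22
ROB	CRC	0.26	0.16
ROB	HHC	0.38	0.18
ROB	LOP	0.49	0.49
ROB	PUS	0.32	0.39
ROB	RAD	0.65	0.35
SMB	BSD	0.33	0.16
SMB	BUR	0.45	0.21
SMB	CMM	0.23	0.04
SMB	CMS	0.03	0.13
SMB	CRC	0.22	0.06
SMB	HHC	0.38	0.02
SMB	LOP	0.47	0.39
SMB	PUS	0.45	0.06
SMB	RAD	0.61	0.21
SMB	ROB	0.61	0.4
WHS	BSD	0.12	0.07
WHS	BUR	0.33	0.39
WHS	CMM	0.43	0.31
WHS	CMS	0.3	0.05
WHS	CRC	0.32	0.4
WHS	HHC	0.4	0.28
WHS	LOP	0.15	0.17
WHS	PUS	0.11	0.42
WHS	RAD	0.18	0.22
WHS	ROB	0.17	0.32
WHS	SMB	0.17	0.14
YEP	BSD	0.25	0.28
YEP	BUR	0.28	0.26
YEP	CMM	0.36	0.36
YEP	CMS	0.17	0.25
YEP	CRC	0.2	0.17
YEP	HHC	0.51	0.22
YEP	LOP	0.27	0.34
YEP	PUS	0.45	0.19
YEP	RAD	0.41	0.43
YEP	ROB	0.36	0.36
YEP	SMB	0.63	0.36
YEP	WHS	0.32	0.17
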