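name	x	y	z	category	subcortical
SMA1	-4	-2	68	SI>ET,SI>CON	FALSE
PreSMA1	6	16	46	SI>ET,SI>CON	FALSE
VLPFC1	-50	4	4	SI>ET,SI>CON	FALSE
VLPFC2	44	14	2	SI>ET,SI>CON	FALSE
VLPFC3	56	14	0	SI>ET,SI>CON	FALSE
DLPFC1	34	40	36	SI>ET,SI>CON	FALSE
APFC	40	46	2	SI>ET,SI>CON	FALSE
INS1	-32	18	4	SI>ET,SI>CON	FALSE
INS2	30	20	6	SI>ET,SI>CON	FALSE
Thal1	-14	-18	6	SI>ET,SI>CON	TRUE
Thal2	14	-16	8	SI>ET,SI>CON	TRUE
LOA1	50	-54	-6	SI>ET,SI>CON	FALSE
PMd1	-20	-2	62	SI>ET,SI>CON,ET>CON	FALSE
PMd2	24	-4	58	SI>ET,SI>CON,ET>CON	FALSE
IPL1	36	-44	50	SI>ET,SI>CON,ET>CON	FALSE
Put1	-24	2	4	SI>ET,SI>CON,ET>CON	TRUE
Put2	24	4	8	SI>ET,SI>CON,ET>CON	TRUE
PreSMA2	-6	6	48	SI>CON,ET>CON	FALSE
PreSMA3	6	4	52	SI>CON,ET>CON	FALSE
PMd3	-32	-12	56	SI>CON,ET>CON	FALSE
PMd4	38	-10	62	SI>CON,ET>CON	FALSE
IPL2	-48	-42	54	SI>CON,ET>CON	FALSE
IPL3	-32	-50	52	SI>CON,ET>CON	FALSE
IPL4	46	-34	40	SI>CON,ET>CON	FALSE
DLPFC2	-56	4	36	SI>CON,ET>CON	FALSE
DLPFC3	52	6	36	SI>CON,ET>CON	FALSE
IPL5	-28	-60	58	SI>CON,ET>CON	FALSE
IPL6	18	-66	58	SI>CON,ET>CON	FALSE
IPL7	-16	-72	56	SI>CON,ET>CON	FALSE
SOG1	30	-68	32	SI>CON,ET>CON	FALSE
SOG2	-26	-74	24	SI>CON,ET>CON	FALSE
SOG3	32	-74	26	SI>CON,ET>CON	FALSE
SOG4	-28	-82	22	SI>CON,ET>CON	FALSE
MOG1	-32	-86	12	SI>CON,ET>CON	FALSE
MOG2	32	-80	6	SI>CON,ET>CON	FALSE
MOG3	40	-74	4	SI>CON,ET>CON	FALSE
LG1	-16	-86	4	SI>CON,ET>CON	FALSE
LG2	18	-90	2	SI>CON,ET>CON	FALSE
LG3	-10	-84	-10	SI>CON,ET>CON	FALSE
LG4	14	-84	-12	SI>CON,ET>CON	FALSE
FG1	-24	-76	-14	SI>CON,ET>CON	FALSE
FG2	22	-76	-14	SI>CON,ET>CON	FALSE
LOA2	-48	-68	-8	SI>CON,ET>CON	FALSE
Cereb1	6	-70	-20	SI>CON,ET>CON	FALSE
M1-1	-40	-20	52	MTR_LvR	FALSE
Cereb2	-26	-62	-24	MTR_LvR	FALSE
Cereb3	28	-58	-24	MTR_LvR	FALSE
Cereb4	-28	-66	-52	MTR_LvR	FALSE
Cereb5	28	-66	-52	MTR_LvR	FALSE
M1-2	40	-22	54	MTR_LvR	FALSE
SMA2	-6	-20	50	MTR_LvR	FALSE
SMA3	8	-24	50	MTR_LvR	FALSE
InsPost1	-36	-32	22	MTR_LvR	FALSE
InsPost2	42	-22	20	MTR_LvR	FALSE
Cereb6	-18	-58	-20	MTR_LvR	FALSE
Cereb7	20	-52	-20	MTR_LvR	FALSE
Thal3	16	-20	2	MTR_LvR	TRUE
PutPost	32	-12	2	MTR_LvR	TRUE
Caudate1	-14	12	12	ETC	TRUE
Caudate2	14	12	12	ETC	TRUE
VS1	-10	14	-6	ETC	TRUE
VS2	10	14	-6	ETC	TRUE
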