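residue	hydropathy	hydrophilicity	volume	mass	charge	polarity	helix_propensity	sheet_propensity	surface_area	isoelectric_point
A	1.8	-0.5	88.6	71.08	0	8.1	1.42	0.83	115	6.00
R	-4.5	3.0	173.4	156.19	1	10.5	0.98	0.93	225	10.76
N	-3.5	0.2	114.1	114.10	0	11.6	0.67	0.89	160	5.41
D	-3.5	3.0	111.1	115.09	-1	13.0	1.01	0.54	150	2.77
C	2.5	-1.0	108.5	103.14	0	5.5	0.70	1.19	135	5.07
Q	-3.5	0.2	143.8	128.13	0	10.5	1.11	1.10	180	5.65
E	-3.5	3.0	138.4	129.12	-1	12.3	1.51	0.37	190	3.22
G	-0.4	0.0	60.1	57.05	0	9.0	0.57	0.75	75	5.97
H	-3.2	-0.5	153.2	137.14	0.1	10.4	1.00	0.87	195	7.59
I	4.5	-1.8	166.7	113.16	0	5.2	1.08	1.60	175	6.02
L	3.8	-1.8	166.7	113.16	0	4.9	1.21	1.30	170	5.98
K	-3.9	3.0	168.6	128.17	1	11.3	1.16	0.74	200	9.74
M	1.9	-1.3	162.9	131.19	0	5.7	1.45	1.05	185	5.74
F	2.8	-2.5	189.9	147.18	0	5.2	1.13	1.38	210	5.48
P	-1.6	0.0	112.7	97.12	0	8.0	0.57	0.55	145	6.30
S	-0.8	0.3	89.0	87.08	0	9.2	0.77	0.75	115	5.68
T	-0.7	-0.4	116.1	101.10	0	8.6	0.83	1.19	140	5.60
W	-0.9	-3.4	227.8	186.21	0	5.4	1.08	1.37	255	5.89
Y	-1.3	-2.3	193.6	163.18	0	6.2	0.69	1.47	230	5.66
V	4.2	-1.5	140.0	99.13	0	5.9	1.06	1.70	155	5.96
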