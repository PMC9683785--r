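group	T5C	T25C	T50C	T75C	T100C	T125C
A	90	102.6	112.1	117.6	120.8	122.6
C	120	134.4	145.3	151.6	155.2	157.2
D	110	119	125.8	129.7	132	133.3
E	140	152.6	162.1	167.6	170.8	172.6
F	230	258.7	280.6	293.1	300.3	304.4
G	30	33.6	36.3	37.9	38.8	39.3
H	180	197.9	211.6	219.4	223.9	226.5
I	220	250.5	273.7	287.1	294.7	299.1
K	200	221.5	237.9	247.3	252.7	255.8
L	220	250.5	273.7	287.1	294.7	299.1
M	190	213.3	231.1	241.3	247.1	250.5
N	120	129	135.8	139.7	142	143.3
P	150	166.1	178.4	185.5	189.6	191.9
Q	150	162.6	172.1	177.6	180.8	182.6
R	210	229.7	244.8	253.4	258.3	261.2
S	80	87.2	92.6	95.8	97.6	98.6
T	120	134.4	145.3	151.6	155.2	157.2
V	170	193.3	211.1	221.3	227.1	230.5
W	270	304.1	330.1	344.9	353.5	358.4
Y	230	256.9	277.4	289.2	295.9	299.8
backbone	15	22.2	27.6	30.8	32.6	33.6
Nterm	40	43.6	46.3	47.9	48.8	49.3
Cterm	35	38.6	41.3	42.9	43.8	44.3
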