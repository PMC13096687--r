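region	min_lat	max_lat	centroid_lon	centroid_lat	hotspot
BZN	-16.3	5.3	-52.4	-5.1	0
COL	-4.2	12.5	-73.1	3.9	1
PER	-18.4	0.0	-74.4	-9.2	1
VEN	0.7	12.2	-66.2	7.1	1
ECU	-5.0	1.4	-78.4	-1.4	1
ETH	3.4	14.9	39.6	8.6	1
TAN	-11.7	-1.0	34.8	-6.4	1
MDG	-25.6	-12.0	46.7	-19.4	1
CHN	18.2	53.6	103.9	36.6	1
NEP	26.4	30.4	84.1	28.2	1
AUT	46.4	49.0	14.1	47.6	0
SPA	36.0	43.8	-3.6	40.2	1
MOR	27.7	35.9	-6.3	31.8	1
TUR	35.8	42.1	35.2	39.0	1
MXC	18.6	23.5	-100.1	21.0	1
CPP	-34.8	-30.3	21.9	-32.4	1
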