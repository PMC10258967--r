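trait	k	f10	f01	f11	pi11_pct	p_lrt
SCZ	458236	154	4295	605	12.0	1.8e-266
RA	203961	450	781	881	41.7	1.8e-266
AF	236293	166	1262	242	14.5	1.2e-51
T2D	475656	2897	4331	1904	20.8	1.8e-266
COA	250069	259	1877	421	16.5	6.2e-259
AOA	249871	239	970	432	26.3	1.1e-217
AD	274668	8	184	80	32.7	1.2e-51
BRC	337234	3	2274	71	3.0	2.8e-24
IS	246666	10	30	39	49.4	1.6e-25
PCA	247201	134	641	293	27.4	2.4e-171
TL	125043	23	17	43	51.8	9.1e-48
BMI	118899	438	11818	768	5.9	1.8e-134
height	139126	3528	5292	2616	22.9	1.8e-266
DBP	214705	841	3624	468	3.3	2.1e-128
SBP	213840	165	13874	642	4.4	6.1e-150
PP	213862	461	1069	409	3.5	2.7e-125
HDL	122159	218	305	227	30.3	1.2e-104
LDL	121447	94	287	178	31.8	1.0e-112
TC	122106	151	367	275	34.7	3.9e-170
TG	121414	162	259	181	30.1	7.3e-86
HbA1c	124962	88	50	106	43.4	3.3e-58
eGFR	236693	805	3413	933	18.1	1.8e-266
AAM	319439	35	6271	340	5.1	7.6e-174
ANM	137069	31	296	85	20.6	2.3e-48
PLT	222492	793	2929	1205	24.5	1.8e-266
RBC	222589	413	2258	890	25.0	1.8e-266
MCV	222587	790	2597	1273	27.3	1.8e-266
HCT	222528	141	1691	457	20.0	1.3e-256
MCH	222441	661	2308	1184	28.5	1.8e-266
MCHC	222580	233	817	338	24.4	2.4e-213
HGB	222563	132	1725	339	15.4	1.9e-226
MONO	222622	147	2524	440	14.1	3.8e-160
NEUT	222435	170	2020	309	12.4	4.3e-201
EO	222395	114	2190	334	12.7	6.9e-184
BASO	222525	143	598	200	21.3	2.7e-90
LYMPH	222490	32	2307	263	10.1	1.3e-160
WBC	222550	343	2451	555	16.6	6.7e-272
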