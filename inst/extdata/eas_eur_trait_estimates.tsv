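trait	type	h2_eas	se_eas	h2_eur	se_eur	p_h2diff	rho_g	rho_se	p_rho
SCZ	binary	0.360	0.020	0.364	0.015	8.73e-1	0.74	0.10	1.33e-2
RA	binary	0.143	0.034	0.115	0.016	4.56e-1	0.70	0.14	2.65e-2
AF	binary	0.095	0.027	0.020	0.003	5.77e-3	NA	NA	NA
T2D	binary	0.066	0.004	0.041	0.002	2.27e-8	0.93	0.04	5.89e-2
COA	binary	0.015	0.003	0.043	0.006	3.00e-5	0.57	0.09	1.66e-6
AOA	binary	0.015	0.003	0.030	0.003	4.07e-4	0.53	0.11	1.21e-5
AD	binary	0.008	0.002	0.040	0.015	3.45e-2	NA	NA	NA
BRC	binary	0.053	0.030	0.106	0.010	9.38e-2	NA	NA	NA
IS	binary	0.010	0.002	0.008	0.001	3.71e-1	0.89	0.20	5.69e-1
PCA	binary	0.038	0.007	0.055	0.007	8.59e-2	0.83	0.14	2.13e-1
TL	continuous	0.075	0.023	0.062	0.014	6.29e-1	0.61	0.20	4.63e-2
BMI	continuous	0.141	0.008	0.181	0.007	1.68e-4	0.84	0.04	1.53e-5
height	continuous	0.327	0.018	0.286	0.015	8.01e-2	0.86	0.04	2.57e-4
DBP	continuous	0.046	0.005	0.106	0.005	2.16e-17	0.73	0.06	6.70e-6
SBP	continuous	0.056	0.006	0.109	0.004	1.99e-13	0.71	0.05	5.62e-9
PP	continuous	0.037	0.004	0.094	0.004	7.07e-24	0.73	0.07	8.80e-5
HDL	continuous	0.154	0.033	0.241	0.061	2.10e-1	NA	NA	NA
LDL	continuous	0.058	0.012	0.171	0.029	3.18e-4	0.77	0.18	1.97e-1
TC	continuous	0.054	0.009	0.183	0.026	2.75e-6	0.92	0.11	4.79e-1
TG	continuous	0.117	0.037	0.209	0.045	1.14e-1	NA	NA	NA
HbA1c	continuous	0.073	0.014	0.039	0.006	2.56e-2	0.98	0.17	9.25e-1
eGFR	continuous	0.071	0.007	0.058	0.004	1.07e-1	0.83	0.05	4.42e-4
AAM	continuous	0.081	0.008	0.125	0.006	1.08e-5	NA	NA	NA
ANM	continuous	0.082	0.013	0.132	0.013	6.54e-3	0.66	0.09	2.34e-4
PLT	continuous	0.011	0.014	0.201	0.018	7.95e-17	0.84	0.07	2.51e-2
RBC	continuous	0.085	0.010	0.151	0.017	8.19e-4	0.92	0.06	1.39e-1
MCV	continuous	0.132	0.018	0.227	0.032	9.67e-3	0.87	0.07	7.48e-2
HCT	continuous	0.052	0.006	0.104	0.010	8.24e-6	0.88	0.08	1.38e-1
MCH	continuous	0.114	0.017	0.224	0.036	5.73e-3	0.87	0.12	2.52e-1
MCHC	continuous	0.040	0.007	0.083	0.014	6.01e-3	0.84	0.15	2.75e-1
HGB	continuous	0.050	0.006	0.111	0.013	2.04e-5	0.79	0.10	3.70e-2
MONO	continuous	0.059	0.010	0.163	0.019	1.27e-6	0.80	0.09	2.99e-2
NEUT	continuous	0.087	0.011	0.026	0.005	4.46e-7	0.77	0.06	2.42e-4
EO	continuous	0.055	0.011	0.130	0.013	1.06e-5	0.76	0.09	5.98e-3
BASO	continuous	0.039	0.014	0.058	0.007	2.25e-1	0.63	0.12	2.07e-3
LYMPH	continuous	0.057	0.010	0.144	0.011	4.85e-9	0.84	0.10	8.26e-2
WBC	continuous	0.070	0.008	0.139	0.013	6.17e-6	0.75	0.06	3.85e-5
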