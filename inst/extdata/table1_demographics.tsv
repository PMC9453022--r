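variable	unit	mci_n	mci_mean	mci_sd	nmci_n	nmci_mean	nmci_sd	printed_p
Age	year	51	38.47	7.93	48	35.45	8.76	0.076
Education	year	51	12.98	2.33	48	13.78	3.21	0.163
BMI	kg/m2	51	27.26	3.06	48	26.78	4.20	0.514
Neck circumference	cm	51	41.17	3.24	48	39.95	2.77	0.048
Waistline	cm	51	99.19	6.92	48	97.04	15.18	0.361
AHI	events/h	51	53.19	23.12	48	49.58	19.23	0.402
Nadir SpO2	%	51	71.25	12.52	48	68.31	12.52	0.244
MSpO2	%	51	92.38	3.57	48	91.82	5.13	0.530
Total sleep time	min	51	366.05	112.36	48	379.20	77.78	0.503
Sleep efficiency	%	51	80.01	22.20	48	85.74	12.14	0.118
N1	%	51	28.94	17.26	48	25.16	16.58	0.270
N2	%	51	39.32	12.68	48	43.16	15.09	0.174
N3	%	51	19.58	14.68	48	21.39	15.68	0.555
REM	%	51	15.45	9.90	48	12.63	8.71	0.137
SpO2 below 90	%	51	24.34	20.02	48	23.23	16.36	0.764
MoCA	points	51	22.23	2.61	48	27.27	1.16	0.001
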