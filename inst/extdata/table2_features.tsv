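id	feature	network	mci_mean	mci_sd	nmci_mean	nmci_sd	weight_svm	weight_lr	weight_rf
1	Olfactory R	DMN	-0.095	0.292	-0.187	0.245	0.45695206	0.61365026	0.07962183
2	Cingulum Ant L	DMN	0.174	0.336	0.293	0.385	-0.45212804	-0.41221711	0.08364737
3	Pallidum L	Basal node network	-0.11	0.383	0.088	0.477	0.03777478	-0.02233599	0.07402411
4	Transverse temporal L	DMN	0.26	0.412	0.489	0.351	-0.28568111	-0.3511914	0.10909707
5	Cerebelum Crus1 R	Cerebellum network	0.059	0.280	-0.088	0.289	0.57115715	0.49502768	0.10136584
6	Cerebelum 4 5 L	Cerebellum network	-0.027	0.221	0.151	0.239	-0.3993657	-0.3675441	0.17269695
7	Vemis 1	Cerebellum network	-0.386	0.348	-0.258	0.272	-0.14545911	-0.44863276	0.09362268
8	Vemis 6	Cerebellum network	-0.123	0.280	0.001	0.335	-0.47500579	-0.24829838	0.07821442
9	Vemis 8	Cerebellum network	-0.419	0.310	-0.286	0.295	-0.37868619	-0.58716901	0.11912403
10	Vemis 10	Cerebellum network	-0.399	0.304	-0.503	0.284	0.56859686	0.84123316	0.08858571
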