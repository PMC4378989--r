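subject	aggregation	age
S01	-0.0509	29
S02	0.4489	58
S03	2.2168	57
S04	1.9162	36
S05	-0.8973	43
S06	0.0698	50
S07	1.2136	40
S08	0.4348	40
S09	0.2215	62
S10	0.1179	41
S11	0.8582	28
S12	-0.9452	53
S13	0.3102	53
S14	0.9259	29
S15	0.564	26
S16	1.2603	41
S17	0.7162	25
S18	0.9014	48
S19	1.53	63
S20	1.6771	39
S21	-0.5238	35
S22	-0.3605	47
S23	0.1647	30
S24	0.5928	40
S25	-0.5253	38
S26	0.3142	63
S27	-0.5396	61
S28	-1.3253	55
S29	1.3715	55
S30	-0.068	65
S31	-0.6657	48
S32	1.5274	34
S33	-0.9948	30
S34	1.6431	57
S35	-0.4521	64
S36	-0.923	64
S37	-2.1364	30
S38	-1.0321	50
S39	0.6888	59
S40	-1.6998	31
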