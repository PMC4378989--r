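subject	met7	met8	met9	met10	met11
S01	-0.6791	-0.9191	-0.6919	-0.3411	-0.8181
S02	-1.6582	-0.219	1.5665	0.0093	0.9676
S03	-0.0397	-0.7366	0.9056	0.0548	2.6463
S04	-0.2114	-3.0063	-1.5118	-1.1766	1.0079
S05	-0.9029	-0.1548	0.1585	0.1764	0.1601
S06	-0.5097	-1.9272	-2.1602	-0.2745	-1.6168
S07	-1.841	-0.7666	-0.2972	1.0641	0.1547
S08	-0.9263	0.7509	1.8608	0.4155	1.1171
S09	0.882	0.7641	0.9751	0.9451	-0.0606
S10	1.2449	0.5804	0.5648	-0.4848	1.6265
S11	-1.0512	1.6078	1.2646	2.043	-1.4573
S12	-0.6651	0.159	-0.1305	0.3361	-1.5782
S13	0.7341	1.2061	1.1922	-0.7155	-0.1788
S14	-0.5089	2.0417	1.3123	0.9996	-0.7342
S15	-0.4272	-0.2435	-0.9269	-0.0269	-0.7207
S16	-0.6238	-0.6667	-0.7267	-0.7301	-0.4159
S17	0.198	0.0092	-0.3205	1.1975	-1.5328
S18	1.5006	0.2526	0.6219	-0.4251	1.5198
S19	-1.1407	-1.0149	1.0895	-2.6626	0.3221
S20	0.4968	0.2005	0.7285	-0.079	-0.0344
S21	1.4084	-0.1432	-1.5054	-0.2584	-1.0562
S22	-0.6234	-0.2608	0.1332	0.0505	-0.5628
S23	-0.7417	-0.3173	-0.9118	-0.4064	-0.6585
S24	0.3766	-0.1412	0.6002	-1.2298	0.2023
S25	-1.3102	0.573	1.2635	-1.023	-1.7401
S26	0.0781	-0.6698	0.8357	-0.2196	2.491
S27	-0.7954	-0.7935	-0.3542	0.9577	1.5981
S28	1.7665	1.0716	0.1359	0.4043	0.474
S29	-0.9364	0.0731	0.8298	-0.9409	-0.7564
S30	0.7039	0.8	0.7419	-0.7278	0.6762
S31	-0.7558	-0.5385	-0.5401	0.3483	-0.8472
S32	-0.4682	-0.2895	0.1109	-1.1522	-0.7047
S33	-0.8445	-1.0323	0.541	-1.0869	1.4055
S34	-1.0915	-1.1517	0.1157	-2.099	0.3323
S35	-1.3234	-0.1759	0.8099	-0.3392	0.4696
S36	-0.5916	-0.2544	-0.4049	-0.5018	-0.739
S37	0.7483	0.8652	0.6949	-0.619	0.0278
S38	-0.8215	-1.4467	-0.4302	0.0851	1.137
S39	-1.7646	-0.0513	0.2897	0.7435	0.4116
S40	-0.3885	0.245	1.0254	-0.7756	-0.492
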