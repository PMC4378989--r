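subject	met1	met2	met3	met4	met5	met6
S01	-1.1046	-1.7135	-1.1628	-1.1123	-0.274	-1.4179
S02	0.539	-0.1717	-1.0227	0.6865	0.9914	0.5672
S03	0.5802	-2.7348	-2.1985	-0.835	-3.9906	0.4794
S04	-0.6575	0.9692	0.825	0.0307	0.7484	0.5456
S05	1.5549	1.3189	-0.5341	-0.0094	1.0421	-0.1793
S06	-1.1876	-0.5611	0.2124	0.222	-0.3431	0.7548
S07	0.1518	0.3385	0.7758	0.6898	-0.3754	-0.7347
S08	-1.0861	-1.2201	0.4404	-0.2471	-2.1081	-0.3412
S09	1.6134	0.5624	-0.69	0.8734	0.3812	1.7533
S10	0.0356	1.5609	1.5727	-0.4632	-0.6911	-1.1785
S11	1.315	1.1967	1.027	-0.1506	-0.439	-0.7107
S12	0.9782	-1.9683	-2.0955	0.6132	-0.179	0.3659
S13	0.8818	1.2908	1.2085	1.1063	0.6174	0.5198
S14	0.4822	0.1383	-0.9918	-1.5618	-0.5717	-1.3623
S15	0.9658	0.5641	-1.2647	-1.3223	0.5418	-1.7558
S16	-0.8146	-0.7278	-1.2052	-0.9362	1.2548	-1.2084
S17	0.284	0.9647	1.0521	0.111	0.1432	-0.2203
S18	-0.1617	-0.2765	-0.0954	-1.2749	-0.4204	-0.1651
S19	1.9356	1.1641	0.0134	1.5816	2.1552	1.4356
S20	1.7232	0.6309	-0.2723	-0.8401	-0.2632	-0.7279
S21	0.3584	1.7219	0.9969	-1.6693	1.297	-1.1572
S22	0.3024	0.6676	-0.1818	-1.8854	-0.3429	-2.1038
S23	-0.3941	0.0301	0.4658	0.7243	-0.1025	0.352
S24	0.7881	1.7219	-0.3778	-1.1754	0.6306	0.5053
S25	0.6707	0.5098	0.9241	-0.4552	0.4462	-1.7848
S26	-0.9492	-1.5199	-1.0041	-0.0241	-1.2415	0.8716
S27	0.0361	0.2909	1.1952	-0.6986	-0.3055	-0.7482
S28	2.1158	-0.1574	-1.584	-0.6906	-0.5148	-1.0625
S29	0.1674	0.7506	1.8881	0.7294	-0.7869	-1.1269
S30	-0.8798	0.3437	1.2714	1.732	1.1915	0.9019
S31	0.9469	1.8554	0.1907	-1.3379	2.106	-1.8237
S32	-0.7046	-1.2533	-1.1626	-0.8202	-1.3427	0.8831
S33	-1.0782	-0.9343	-1.0787	1.0015	0.8287	-0.8376
S34	-0.0517	-0.2577	-1.8751	-2.3356	-0.1807	0.5731
S35	0.5809	0.9471	1.1378	1.6947	0.5409	0.8786
S36	-0.3173	-1.7993	-0.1743	1.0011	-0.5926	0.7622
S37	-2.9536	-1.0714	0.1083	1.7421	0.1889	2.5049
S38	-1.0031	-0.3916	0.1995	-0.1184	-0.0541	-0.0435
S39	0.3736	-0.5514	-1.1466	-0.9521	-0.4791	-1.0933
S40	0.1602	-0.7141	-0.5664	1.1702	-0.8144	1.261
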