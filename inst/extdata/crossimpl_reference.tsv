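id	offset	exponent	cf	height	sd	r_squared	n_peaks
1	0.929905	2.011758	8.324805	0.802459	1.445583	0.999458	1
2	-0.605930	0.996791	9.496761	0.505863	0.905643	0.998168	3
3	-0.953331	2.010177	10.187162	0.489767	1.376571	0.999270	2
4	0.597699	1.992942	11.649435	0.604028	1.001282	0.999269	3
5	0.516868	1.003782	9.517514	0.803022	1.350652	0.997880	1
6	0.453985	0.503642	10.773680	0.583155	0.974431	0.992178	1
7	0.396495	1.992960	11.428993	0.847446	1.449239	0.999421	1
8	-0.878245	0.501273	11.284489	0.794337	0.967856	0.995338	3
9	-0.947445	2.010105	10.592961	0.512535	1.422673	0.999331	2
10	-0.144501	0.987602	8.367826	0.568605	0.842614	0.997052	1
11	-0.456835	0.998144	10.371267	0.740046	1.133804	0.998065	3
12	-0.099876	1.001973	10.710223	0.490400	0.920517	0.998044	4
13	-0.178729	1.006717	12.774918	0.408158	1.140638	0.997922	2
14	0.558613	1.499899	10.553046	0.594701	0.814449	0.998879	1
15	0.041340	2.001822	9.657812	0.901760	1.017102	0.999310	1
16	-0.478096	0.501998	10.833322	0.494818	0.750354	0.993039	2
17	0.843924	1.027763	7.897845	0.620478	1.152644	0.998145	3
18	0.483511	0.520396	7.978441	0.807867	1.191764	0.996581	3
19	-0.383819	1.504065	10.691300	0.755660	1.347977	0.998954	2
20	0.054880	0.495462	9.984955	0.800205	1.081943	0.995622	1
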