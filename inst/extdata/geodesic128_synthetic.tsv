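sensor	x	y	z
1	0.088302	0	0.996094
2	-0.125005	0.114515	0.985525
3	0.019443	-0.221542	0.974957
4	0.160926	0.209899	0.964389
5	-0.295787	-0.05232	0.95382
6	0.280193	-0.178236	0.943252
7	-0.093638	0.34833	0.932683
8	-0.178332	-0.343368	0.922115
9	0.386246	0.141056	0.911547
10	-0.401041	0.165544	0.900978
11	0.192918	-0.412254	0.89041
12	0.14224	0.453483	0.879841
13	-0.427702	-0.247862	0.869273
14	0.500518	-0.110038	0.858704
15	-0.304691	0.433392	0.848136
16	-0.07021	-0.541803	0.837568
17	0.429888	0.36231	0.826999
18	-0.57695	0.023859	0.816431
19	0.4197	-0.417657	0.805862
20	-0.028002	0.605577	0.795294
21	-0.397139	-0.475906	0.784726
22	0.62734	0.084408	0.774157
23	-0.530031	0.368781	0.763589
24	0.144418	-0.641953	0.75302
25	0.333061	0.581236	0.742452
26	-0.649193	-0.20711	0.731884
27	0.628742	-0.290495	0.721315
28	-0.271574	0.648912	0.710747
29	-0.241644	-0.671832	0.700178
30	0.641037	0.336911	0.68961
31	-0.709852	0.187115	0.679042
32	0.402241	-0.625577	0.668473
33	0.127557	0.74222	0.657905
34	-0.602617	-0.4667	0.647336
35	0.768423	-0.063662	0.636768
36	-0.529453	0.572323	0.6262
37	0.003844	-0.788025	0.615631
38	0.53494	0.589693	0.605063
39	-0.800668	-0.074206	0.594494
40	0.646652	-0.490786	0.583926
41	-0.146642	0.806075	0.573358
42	-0.440252	-0.699605	0.562789
43	0.804049	0.220357	0.552221
44	-0.747873	0.383796	0.541652
45	0.294542	-0.794478	0.531084
46	0.321939	0.790834	0.520516
47	-0.77733	-0.368391	0.509947
48	0.827927	-0.255259	0.499379
49	-0.4411	0.752659	0.48881
50	-0.184386	-0.858654	0.478242
51	0.720598	0.511879	0.467673
52	-0.882585	0.109995	0.457105
53	0.57996	-0.68136	0.446537
54	0.032798	0.899364	0.435968
55	-0.635236	-0.644601	0.4254
56	0.908711	0.046463	0.414831
57	-0.705098	0.582587	0.404263
58	0.127021	-0.910423	0.393695
59	0.523847	0.760788	0.383126
60	-0.904377	-0.208095	0.372558
61	0.811056	-0.459512	0.361989
62	-0.288897	0.890529	0.351421
63	0.446542	-0.839659	0.309147
64	0.868917	0.368639	0.330284
65	-0.588103	-0.782776	0.203463
66	-0.390138	-0.855343	0.340853
67	0.238758	0.924037	0.298579
68	-0.80295	-0.521844	0.288011
69	0.947644	-0.158106	0.277442
70	-0.593806	0.759061	0.266874
71	-0.075107	-0.963673	0.256305
72	0.708336	0.66172	0.245737
73	-0.971908	-0.009483	0.235169
74	-0.714955	0.697725	0.044937
75	0.055902	-0.997845	0.034369
76	-0.893148	0.316335	0.319716
77	0.964507	0.180329	0.192895
78	-0.834722	0.519612	0.182327
79	-0.42902	0.893966	0.129484
80	0.446313	0.88024	0.16119
81	-0.925252	-0.348169	0.150621
82	0.918878	-0.368848	0.140053
83	0.265016	-0.948823	0.171758
84	-0.287903	-0.950248	0.118916
85	0.855214	0.506824	0.108348
86	-0.974034	0.204197	0.097779
87	0.997961	-0.031519	0.055506
88	0.11848	0.989994	0.076642
89	-0.756668	-0.650452	0.066074
90	0.580862	-0.809317	0.087211
91	0.724918	-0.651191	0.2246
92	-0.09489	0.972207	0.214032
93	0.633008	0.773779	0.0238
94	-0.989635	-0.142997	0.013232
95	0.826389	-0.563094	0.002664
96	-0.228982	0.973398	-0.007905
97	-0.488609	-0.872307	-0.018473
98	0.949282	0.313083	-0.029042
99	-0.911124	0.410224	-0.03961
100	0.394545	-0.917505	-0.050178
101	0.328647	0.942497	-0.060747
102	-0.878366	-0.472638	-0.071315
103	0.966155	-0.24462	-0.081884
104	-0.546667	0.832231	-0.092452
105	-0.158903	-0.981905	-0.10302
106	0.779534	0.615975	-0.113589
107	-0.989627	0.072274	-0.124157
108	0.679953	-0.720773	-0.134726
109	-0.014479	0.989283	-0.145294
110	-0.656504	-0.738044	-0.155862
111	0.980911	0.100572	-0.166431
112	-0.78975	0.587338	-0.176999
113	0.185227	-0.964629	-0.187568
114	0.513928	0.834638	-0.198136
115	-0.940632	-0.267682	-0.208704
116	0.872339	-0.436971	-0.219273
117	-0.347197	0.90919	-0.229841
118	-0.357196	-0.90256	-0.24041
119	0.870646	0.423067	-0.250978
120	-0.925079	0.275358	-0.261547
121	0.494619	-0.825412	-0.272115
122	0.19223	0.939754	-0.282683
123	-0.773966	-0.561231	-0.293252
124	0.94652	-0.108596	-0.30382
125	-0.622327	0.716846	-0.314389
126	-0.025243	-0.945392	-0.324957
127	0.654647	0.677392	-0.335525
128	-0.936464	-0.057047	-0.346094
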