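sample	ihc	fish	ihc_revised	fish_revised	snp_cn	relation	status
1	0	NA	NA	NA	1.98	balance	normal
2	0	NA	NA	NA	2.35	HER2plus	amp
3	0	1.92	NA	NA	1.81	balance	normal
4	0	NA	NA	NA	2.06	balance	normal
5	0	NA	NA	NA	2.04	balance	normal
6	0	NA	NA	NA	1.72	centplus	del
7	0	NA	NA	NA	1.67	balance	del
8	0	NA	NA	NA	1.83	balance	normal
9	0	NA	NA	NA	1.51	centplus	del
10	0	NA	NA	NA	2.51	balance	amp
11	0	NA	NA	NA	1.78	balance	del
12	0	NA	NA	NA	1.85	balance	normal
13	1	NA	NA	NA	1.97	balance	normal
14	1	NA	NA	NA	2.08	balance	normal
15	1	0.83	NA	NA	2.33	balance	amp
16	1	0.80	NA	NA	1.70	balance	del
17	1	0.80	NA	NA	1.80	centplus	normal
18	1	0.86	NA	NA	2.49	balance	amp
19	1	NA	NA	NA	2.06	balance	normal
20	1	NA	NA	NA	2.09	balance	normal
21	1	NA	NA	NA	1.96	balance	normal
22	1	NA	NA	NA	1.97	balance	normal
23	1	NA	NA	NA	2.13	balance	normal
24	1	NA	NA	NA	1.90	balance	normal
25	1	NA	NA	NA	1.87	balance	normal
26	1	NA	NA	NA	4.46	balance	amp
27	1	NA	NA	NA	2.34	balance	amp
28	2	1.41	NA	NA	2.45	balance	amp
29	2	1.54	NA	NA	2.16	balance	normal
30	2	3.05	NA	NA	2.04	balance	normal
31	2	2.69	NA	NA	2.48	balance	amp
32	2	2.42	NA	NA	1.75	centplus	del
33	2	1.73	NA	NA	1.99	balance	normal
34	2	2.65	NA	NA	1.92	balance	normal
35	2	1.50	NA	NA	1.91	balance	normal
36	2	1.57	NA	NA	2.00	balance	normal
37	2	1.68	NA	NA	1.79	balance	del
38	2	1.90	NA	NA	1.84	balance	normal
39	2	1.60	NA	NA	2.05	balance	normal
40	2	1.58	NA	NA	1.89	balance	normal
41	2	2.13	NA	NA	2.73	balance	amp
42	2	1.54	NA	NA	2.04	balance	normal
43	2	1.82	NA	NA	1.54	balance	del
44	2	1.90	NA	NA	1.77	balance	del
45	2	1.66	NA	NA	2.33	balance	amp
46	2	1.48	NA	NA	2.04	balance	normal
47	2	1.73	NA	NA	1.98	balance	normal
48	2	1.67	NA	NA	2.36	balance	amp
49	2	0.93	3	8.8	11.10	HER2plus	amp
50	2	1.81	NA	NA	2.04	balance	normal
51	2	1.58	NA	NA	2.65	HER2plus	amp
52	2	1.60	NA	NA	2.23	balance	amp
53	2	2.27	NA	NA	8.03	HER2plus	amp
54	2	1.87	NA	NA	2.91	balance	amp
55	2	1.24	NA	NA	2.66	balance	amp
56	2	7.38	NA	NA	7.01	HER2plus	amp
57	2	1.00	NA	NA	1.88	balance	normal
58	2	8.60	NA	NA	7.98	HER2plus	amp
59	2	3.24	NA	NA	3.18	HER2plus	amp
60	3	NA	1	1.65	2.00	balance	normal
61	3	4.11	NA	NA	5.28	HER2plus	amp
62	3	7.00	NA	NA	4.58	HER2plus	amp
63	3	NA	2	1.50	2.05	balance	normal
64	3	NA	NA	NA	3.15	HER2plus	amp
65	3	1.35	NA	NA	3.75	HER2plus	amp
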