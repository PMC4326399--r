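sample	polyploid	her2_estimate	fish_3d
1	No	normal	NA
2	Yes	5+	NA
3	Yes	3+	NA
4	No	normal	NA
5	Yes	4+	4-5
6	Yes	3+	NA
7	Yes	3+	NA
8	Yes	4+	NA
9	Yes	3+	NA
10	No	3	NA
11	Yes	3+	NA
12	Yes	5+	NA
13	No	normal	NA
14	No	normal	NA
15	Yes	5+	NA
16	Yes	3+	NA
17	Yes	3+	NA
18	No	3+	NA
19	No	normal	NA
20	No	normal	NA
21	Yes	5+	NA
22	Yes	4	NA
23	Yes	4+	NA
24	Yes	3+	NA
25	No	normal	NA
26	Yes	6+	NA
27	Yes	4+	5-7
28	Yes	4+	NA
29	Yes	4+	4-6
30	Yes	5+	NA
31	Yes	5+	5-7
32	Yes	3+	NA
33	No	normal	NA
34	Yes	5+	5-7
35	No	normal	NA
36	Yes	5+	4-5
37	Yes	3+	NA
38	Yes	3+	NA
39	No	normal	NA
40	No	normal	NA
41	Yes	5+	NA
42	No	normal	NA
43	Yes	UPD(2) or amp	32
44	Yes	5+	NA
45	Yes	8+	8
46	Yes	4+	NA
47	No	normal	NA
48	Yes	5+	NA
49	Yes	25+	NA
50	Yes	5+	NA
51	No	3	NA
52	No	3	NA
53	Yes	7+	NA
54	Yes	7+	NA
55	Yes	7+	5-6
56	Yes	12+	NA
57	No	normal	NA
58	Yes	12+	NA
59	Yes	6+	NA
60	No	normal	NA
61	Yes	8+	NA
62	Yes	8+	NA
63	No	normal	NA
64	Yes	7+	NA
65	Yes	9+	NA
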