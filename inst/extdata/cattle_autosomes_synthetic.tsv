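chrom	length
1	158500000
2	136200000
3	121000000
4	120800000
5	120100000
6	117800000
7	110700000
8	113400000
9	105700000
10	103300000
11	106300000
12	87200000
13	83500000
14	82400000
15	85000000
16	81000000
17	75200000
18	66000000
19	64100000
20	72000000
21	69900000
22	60500000
23	52500000
24	62300000
25	42400000
26	51700000
27	45600000
28	45900000
29	51100000
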