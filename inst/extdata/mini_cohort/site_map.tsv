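index	sense_c_pos	antisense_c_pos
1	23	24
2	40	41
3	57	58
4	74	75
5	91	92
6	108	109
7	125	126
8	142	143
9	159	160
10	176	177
11	193	194
12	210	211
13	227	228
14	244	245
15	261	262
16	278	279
17	295	296
18	312	313
19	329	330
20	346	347
21	379	380
22	396	397
23	413	414
24	430	431
25	447	448
26	464	465
27	481	482
28	498	499
29	515	516
30	532	533
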