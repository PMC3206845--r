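sample_id	strand	clone_id	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20
HCC_01	antisense	1	0	0	0	1	1	0	0	1	1	1	1	0	0	1	0	0	1	0	0	0
HCC_01	antisense	2	0	1	1	1	1	1	0	1	1	0	1	0	0	0	1	1	1	1	0	1
HCC_01	antisense	3	0	0	1	1	0	1	0	1	0	0	0	1	0	1	0	0	1	0	1	1
HCC_01	antisense	4	1	1	0	1	1	0	0	1	0	0	1	1	0	1	0	1	1	1	1	0
HCC_01	antisense	5	1	1	1	1	0	0	0	1	0	1	0	1	1	0	0	1	1	1	1	0
HCC_01	antisense	6	1	1	0	1	1	0	1	0	1	0	0	1	0	1	0	0	1	1	1	1
HCC_01	antisense	7	1	1	1	0	0	0	0	0	1	0	1	1	0	0	1	0	1	0	1	1
HCC_01	antisense	8	1	0	1	1	1	0	1	1	0	0	0	0	1	0	0	0	1	1	1	1
HCC_01	antisense	9	1	1	0	0	1	0	0	0	1	0	0	1	1	1	1	0	1	1	1	0
HCC_01	antisense	10	0	1	1	1	1	0	0	0	0	1	0	0	1	1	1	1	1	0	0	0
HCC_01	antisense	11	1	0	1	0	1	1	1	0	0	0	0	0	1	0	1	1	0	1	1	1
HCC_01	antisense	12	1	0	1	0	0	1	1	0	1	1	1	1	0	1	1	1	1	1	0	0
HCC_01	antisense	13	0	0	1	1	1	0	1	0	0	1	1	1	0	1	0	0	1	1	1	1
HCC_01	antisense	14	1	0	0	0	0	1	1	1	0	0	0	0	1	1	1	1	1	1	1	0
HCC_01	antisense	15	1	1	0	0	0	1	1	0	0	1	1	1	1	0	1	0	1	0	1	1
HCC_01	antisense	16	1	0	1	1	0	0	0	0	1	1	0	1	1	1	0	1	0	1	0	0
HCC_01	antisense	17	0	1	1	0	1	0	0	0	1	1	1	1	1	1	1	0	0	0	1	0
HCC_01	antisense	18	0	0	0	0	0	1	1	1	1	1	0	0	1	1	1	1	1	0	0	1
HCC_02	antisense	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	6	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	7	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	8	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	9	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	10	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	11	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
HCC_02	antisense	12	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_01	antisense	1	1	1	0	1	0	0	0	0	1	0	1	0	1	0	0	0	0	1	0	1
ADJ_01	antisense	2	1	0	0	1	0	0	1	1	0	1	0	1	0	0	0	0	1	0	0	0
ADJ_01	antisense	3	0	0	0	0	0	0	1	1	0	1	1	0	0	1	0	0	1	0	1	0
ADJ_01	antisense	4	0	0	1	0	0	1	0	0	0	0	0	1	0	1	0	0	0	1	0	0
ADJ_01	antisense	5	0	0	0	1	0	0	1	1	1	0	0	0	0	0	0	1	0	0	0	0
ADJ_01	antisense	6	0	1	0	1	1	0	0	0	0	0	0	0	1	0	0	0	0	1	0	0
ADJ_01	antisense	7	1	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_01	antisense	8	0	1	0	0	1	0	0	0	0	0	0	1	0	0	0	1	0	0	1	0
ADJ_01	antisense	9	0	0	0	0	1	0	0	0	0	0	0	0	0	1	0	1	1	0	0	0
ADJ_01	antisense	10	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0
ADJ_01	antisense	11	1	0	0	1	0	0	0	0	0	0	1	1	0	0	1	0	0	1	0	0
ADJ_01	antisense	12	1	1	0	0	0	0	1	0	0	1	0	0	0	1	0	0	0	0	0	0
ADJ_01	antisense	13	1	0	0	0	0	0	1	1	1	0	0	0	0	0	0	0	1	0	1	0
ADJ_01	antisense	14	1	1	0	0	0	0	0	1	1	0	0	1	1	0	1	1	1	0	0	0
ADJ_01	antisense	15	1	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	1	0	0
ADJ_01	antisense	16	0	1	1	0	0	0	1	0	1	0	0	0	1	0	0	0	0	1	0	0
ADJ_01	antisense	17	1	0	0	0	0	1	0	0	0	0	0	1	0	0	0	0	1	0	0	0
ADJ_02	antisense	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	2	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	4	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	5	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	6	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	7	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	8	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	9	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	10	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	11	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	12	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
ADJ_02	antisense	13	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NL_01	antisense	1	1	0	0	0	0	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0
NL_01	antisense	2	0	0	0	0	0	1	0	0	0	0	0	1	1	0	1	0	0	0	0	0
NL_01	antisense	3	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	1	0	0
NL_01	antisense	4	0	1	0	0	0	0	0	0	0	0	0	0	0	1	0	1	0	0	1	0
NL_01	antisense	5	1	0	0	1	0	0	0	0	0	0	0	1	1	0	1	0	1	0	0	0
NL_01	antisense	6	0	0	0	0	0	0	1	1	0	0	0	0	0	0	0	0	1	0	0	0
NL_01	antisense	7	0	0	0	0	1	1	1	0	1	0	0	1	0	0	0	0	0	1	0	0
NL_01	antisense	8	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0
NL_01	antisense	9	0	1	0	0	0	0	0	1	0	0	0	0	0	1	1	0	0	0	0	0
NL_02	antisense	1	1	1	0	0	0	0	0	0	0	0	1	0	0	0	1	0	1	0	0	0
NL_02	antisense	2	0	0	0	0	0	0	1	0	0	0	1	0	0	0	0	1	1	1	0	1
NL_02	antisense	3	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0
NL_02	antisense	4	0	0	1	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	1
NL_02	antisense	5	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1	0	0
NL_02	antisense	6	0	0	0	1	0	0	0	1	0	0	1	1	1	0	0	0	0	0	0	0
NL_02	antisense	7	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0
NL_02	antisense	8	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	1	0
NL_02	antisense	9	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NL_02	antisense	10	0	0	0	0	1	1	1	1	0	0	1	0	0	0	0	1	0	0	0	0
NL_02	antisense	11	0	0	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NL_02	antisense	12	0	0	0	0	1	1	0	1	0	0	0	0	0	0	0	0	1	0	0	1
NL_02	antisense	13	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NL_02	antisense	14	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NL_02	antisense	15	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
NL_02	antisense	16	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	1	0	0
NL_02	antisense	17	0	0	0	0	0	0	0	0	0	0	1	0	0	1	0	0	1	0	0	0
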