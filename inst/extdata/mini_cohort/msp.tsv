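sample_id	assay	replicate	cq
HCC_01	sense	1	31.6149
HCC_01	sense	2	31.5149
HCC_01	antisense	1	31.3208
HCC_01	antisense	2	31.4991
HCC_01	bs_actin	1	30.7309
HCC_01	bs_actin	2	30.9536
HCC_02	sense	1	31.1102
HCC_02	sense	2	31.4527
HCC_02	antisense	1	
HCC_02	antisense	2	
HCC_02	bs_actin	1	30.8115
HCC_02	bs_actin	2	31.0199
HCC_03	sense	1	
HCC_03	sense	2	
HCC_03	antisense	1	32.522
HCC_03	antisense	2	33.0364
HCC_03	bs_actin	1	31.0036
HCC_03	bs_actin	2	30.9266
HCC_04	sense	1	31.66
HCC_04	sense	2	31.7488
HCC_04	antisense	1	32.5032
HCC_04	antisense	2	32.4664
HCC_04	bs_actin	1	30.7778
HCC_04	bs_actin	2	30.9354
ADJ_01	sense	1	32.534
ADJ_01	sense	2	32.9757
ADJ_01	antisense	1	32.1505
ADJ_01	antisense	2	31.9303
ADJ_01	bs_actin	1	30.4359
ADJ_01	bs_actin	2	30.1845
ADJ_02	sense	1	33.1786
ADJ_02	sense	2	34.1078
ADJ_02	antisense	1	
ADJ_02	antisense	2	
ADJ_02	bs_actin	1	30.2654
ADJ_02	bs_actin	2	30.1501
ADJ_03	sense	1	
ADJ_03	sense	2	
ADJ_03	antisense	1	32.4377
ADJ_03	antisense	2	32.4718
ADJ_03	bs_actin	1	30.3487
ADJ_03	bs_actin	2	30.5234
ADJ_04	sense	1	
ADJ_04	sense	2	
ADJ_04	antisense	1	34.315
ADJ_04	antisense	2	35.0082
ADJ_04	bs_actin	1	30.6545
ADJ_04	bs_actin	2	30.8224
CIR_01	sense	1	31.9938
CIR_01	sense	2	31.3016
CIR_01	antisense	1	
CIR_01	antisense	2	
CIR_01	bs_actin	1	30.4141
CIR_01	bs_actin	2	30.6012
CIR_02	sense	1	31.6143
CIR_02	sense	2	31.586
CIR_02	antisense	1	
CIR_02	antisense	2	
CIR_02	bs_actin	1	30.6896
CIR_02	bs_actin	2	30.5911
CIR_03	sense	1	
CIR_03	sense	2	
CIR_03	antisense	1	33.2626
CIR_03	antisense	2	32.9634
CIR_03	bs_actin	1	30.8395
CIR_03	bs_actin	2	30.6611
HEP_01	sense	1	
HEP_01	sense	2	
HEP_01	antisense	1	32.796
HEP_01	antisense	2	32.8577
HEP_01	bs_actin	1	31.0133
HEP_01	bs_actin	2	30.6512
HEP_02	sense	1	
HEP_02	sense	2	
HEP_02	antisense	1	32.813
HEP_02	antisense	2	33.1744
HEP_02	bs_actin	1	30.5406
HEP_02	bs_actin	2	30.4718
HEP_03	sense	1	
HEP_03	sense	2	
HEP_03	antisense	1	32.6691
HEP_03	antisense	2	32.2374
HEP_03	bs_actin	1	30.6694
HEP_03	bs_actin	2	30.5026
NL_01	sense	1	
NL_01	sense	2	
NL_01	antisense	1	33.6116
NL_01	antisense	2	33.7146
NL_01	bs_actin	1	30.9243
NL_01	bs_actin	2	30.7629
NL_02	sense	1	
NL_02	sense	2	
NL_02	antisense	1	34.4795
NL_02	antisense	2	33.9693
NL_02	bs_actin	1	31.1434
NL_02	bs_actin	2	30.979
NLV_01	sense	1	
NLV_01	sense	2	
NLV_01	antisense	1	
NLV_01	antisense	2	
NLV_01	bs_actin	1	31.1271
NLV_01	bs_actin	2	30.9731
ML_01	sense	1	
ML_01	sense	2	
ML_01	antisense	1	
ML_01	antisense	2	
ML_01	bs_actin	1	29.9201
ML_01	bs_actin	2	30.4867
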