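sample_id	group	age	sex	hbv	hcv	stage	grade	afp_ng_ml	tumor_size_cm
HCC_01	HCC	73.9	M	TRUE	TRUE	2	2	11.51	8.4
HCC_02	HCC	61	M	TRUE	FALSE	1	2	66.91	6.5
HCC_03	HCC	63.8	M	FALSE	FALSE	2	2	548.27	5.9
HCC_04	HCC	57.8	M	TRUE	FALSE	4	2	15.39	10.9
ADJ_01	adjacent_non_HCC	74.6	M	FALSE	FALSE	unknown	unknown	1.72	
ADJ_02	adjacent_non_HCC	45.1	F	FALSE	FALSE	unknown	unknown	3.78	
ADJ_03	adjacent_non_HCC	45.8	M	FALSE	FALSE	unknown	unknown	12.07	
ADJ_04	adjacent_non_HCC	57.1	M	FALSE	FALSE	unknown	unknown	3.22	
CIR_01	cirrhosis	56	F	FALSE	FALSE	unknown	unknown	2.4	
CIR_02	cirrhosis	67.6	M	FALSE	TRUE	unknown	unknown	19.43	
CIR_03	cirrhosis	53.8	M	FALSE	FALSE	unknown	unknown	43.44	
HEP_01	hepatitis	41.7	F	TRUE	FALSE	unknown	unknown	1.52	
HEP_02	hepatitis	57.1	F	TRUE	TRUE	unknown	unknown	3.32	
HEP_03	hepatitis	48.6	F	FALSE	FALSE	unknown	unknown	2.14	
NL_01	normal_liver	63.9	F	FALSE	FALSE	unknown	unknown	10.08	
NL_02	normal_liver	77.5	F	FALSE	FALSE	unknown	unknown	1.96	
NLV_01	nonliver	68.7	M	FALSE	FALSE	unknown	unknown	21.57	
ML_01	mouse_liver	0	F	FALSE	FALSE	unknown	unknown		
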