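sample_id	group	frac_sense	frac_antisense	true_copies_sense	true_copies_antisense	input_actual	truth_pos_sense	truth_pos_antisense
HCC_01	HCC	0.540493	0.530331	92.627342	90.885948	171.375755	TRUE	TRUE
HCC_02	HCC	0.784656	0	109.825464	0	139.966428	TRUE	FALSE
HCC_03	HCC	0	0.349497	0	41.191733	117.859897	FALSE	TRUE
HCC_04	HCC	0.472758	0.286937	77.951898	47.312385	164.887568	TRUE	TRUE
ADJ_01	adjacent_non_HCC	0.189481	0.27943	35.753786	52.72669	188.693649	TRUE	TRUE
ADJ_02	adjacent_non_HCC	0.117884	0	23.793012	0	201.834765	TRUE	FALSE
ADJ_03	adjacent_non_HCC	0	0.284662	0	49.83946	175.083159	FALSE	TRUE
ADJ_04	adjacent_non_HCC	0	0.065621	0	9.983198	152.134073	FALSE	TRUE
CIR_01	cirrhosis	0.449354	0	78.294151	0	174.237267	TRUE	FALSE
CIR_02	cirrhosis	0.437399	0	74.07492	0	169.35327	TRUE	FALSE
CIR_03	cirrhosis	0	0.199723	0	31.068211	155.556551	FALSE	TRUE
HEP_01	hepatitis	0	0.229684	0	39.051429	170.022232	FALSE	TRUE
HEP_02	hepatitis	0	0.171033	0	30.697765	179.484343	FALSE	TRUE
HEP_03	hepatitis	0	0.273802	0	44.408721	162.193039	FALSE	TRUE
NL_01	normal_liver	0	0.152652	0	21.078541	138.082087	FALSE	TRUE
NL_02	normal_liver	0	0.100409	0	13.43613	133.814507	FALSE	TRUE
NLV_01	nonliver	0	0	0	0	132.913706	FALSE	FALSE
ML_01	mouse_liver	0	0	0	0	195.461733	FALSE	FALSE
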