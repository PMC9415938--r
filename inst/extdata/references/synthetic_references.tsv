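name	kind	label	group	length	frozen
GAF_CcaS_1	domain	GAF	CcaS	160	85,86,40,90,125
GAF_CcaS_2	domain	GAF	CcaS	160	85,86,40,90,125
GAF_CcaS_3	domain	GAF	CcaS	160	85,86,40,90,125
GAF_RcaE_1	domain	GAF	RcaE	160	85,86,40,90,125
GAF_RcaE_2	domain	GAF	RcaE	160	85,86,40,90,125
GAF_RcaE_3	domain	GAF	RcaE	160	85,86,40,90,125
GAF_RfpA_1	domain	GAF	RfpA	160	85,86,40,90,125
GAF_RfpA_2	domain	GAF	RfpA	160	85,86,40,90,125
GAF_RfpA_3	domain	GAF	RfpA	160	85,86,40,90,125
PAS_ref	domain	PAS		110	
HK_ref	domain	HisKinase		220	
LNK_ref	domain	PBS-linker		190	
PBP_ref	domain	phycobiliprotein		160	30,31,32,33,34,84
ccaS_ref	gene	ccaS		435	110,111,65,115,150
rcaE_ref	gene	rcaE		535	220,221,175,225,260
rfpA_ref	gene	rfpA		535	220,221,175,225,260
cpcG_ref	gene	cpcG		241	
cpcL_ref	gene	cpcL		233	209,210,211,212,213,214,215,216,217,218,219,220,221,222,223,224,225,226,227,228,229
apcE_ref	gene	apcE		760	30,31,32,33,34,84
apcE_farlip_ref	gene	apcE		560	30,31,32,33,34,84
rfpB_ref	gene	rfpB		230	
rfpC_ref	gene	rfpC		140	
apcD_ref	gene	apcD		160	
apcB_ref	gene	apcB		160	
psaA_ref	gene	psaA		380	
psaB_ref	gene	psaB		380	
psbA_ref	gene	psbA		350	
psbB_ref	gene	psbB		380	
psbC_ref	gene	psbC		380	
psbD_ref	gene	psbD		350	
chlF_ref	gene	chlF		320	
pebA_ref	gene	pebA		240	
pebB_ref	gene	pebB		240	
cpeA_ref	gene	cpeA		164	
cpeB_ref	gene	cpeB		177	
pecA_ref	gene	pecA		162	
pecB_ref	gene	pecB		172	
cpcA_ref	gene	cpcA		162	
cpcB_ref	gene	cpcB		172	
cpcS_ref	gene	cpcS		200	
cpcE_ref	gene	cpcE		270	
cpcF_ref	gene	cpcF		210	
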