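marker	ddbj_id	info	role	allele	tag	dye	sequence
SSR08A04	DY293653	(aaac)n	forward	-	F9GCC	VIC	CTAGTATTAGGACGCCCAAACACTTATTCGGGATCAG
SSR08A04	DY293653	(aaac)n	reverse	-	-	-	gtttcttAATGCCATTATCAAACCGCC
SSR08A09	CX663959	(cagg)n	forward	-	F9GTC	PET	CTAGTATGAGGACGTCCATCATTGCATCAGCATCAC
SSR08A09	CX663959	(cagg)n	reverse	-	-	-	gtttcttAGTTCTACATCATAACCTGCC
SSR08B15	DY292389	(acc)n	forward	-	F9GAC	NED	CTAGTATCAGGACGACCCCATACTTGAAACCAAACC
SSR08B15	DY292389	(acc)n	reverse	-	-	-	gtttcttAGCAGCATGACTTAATCCA
SSR08B25	DY289996	(tta)n	forward	-	F9TAC	6-FAM	CTAGTATCAGGACTACCGTTGACTCTCAAGAGATCTG
SSR08B25	DY289996	(tta)n	reverse	-	-	-	gtttcttCTTCACAGTCCGCAGCATTA
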