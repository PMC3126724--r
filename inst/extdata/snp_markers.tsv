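marker	ddbj_id	info	role	allele	tag	dye	sequence
LLL0729	DC891931	(C/G)	lso	-	-	-	gtttcttGAAGTAGAAGGATGATAATCAC
LLL0729	DC891931	(C/G)	aso	C	F9GAC	NED	CTAGTATCAGGACGACATGGACACAACTCAAGTtC
LLL0729	DC891931	(C/G)	aso	G	F9GTC	PET	CTAGTATGAGGACGTCAATGGACACAACTCAAGTtG
MAPGR75R	DC893380	(A/T)	lso	-	-	-	gtttcttGGTTGGTATATCTACGAGAC
MAPGR75R	DC893380	(A/T)	aso	T	F9GTC	PET	CTAGTATGAGGACGTCTATCCGATTGAGCCTTTcT
MAPGR75R	DC893380	(A/T)	aso	A	F9TAC	6-FAM	CTAGTATCAGGACTACATCCGATTGAGCCTTTcA
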