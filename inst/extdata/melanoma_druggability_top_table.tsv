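gene	protein_change	type	classification	score	cosmic_entity	patient_ids
EPHA2	p.S790F	SNP	Missense_Mutation	1.768360		26, 52
EPHA2	p.E607K	SNP	Missense_Mutation	1.737764		48, 87
GART	p.S635F	SNP	Missense_Mutation	0		50, 56
KDR	p.S1100F	SNP	Missense_Mutation	2.679266		16, 45, 75
KIT	p.K642E	SNP	Missense_Mutation	2.454228	yes	3, 27, 31, 70
KIT	p.V559A	SNP	Missense_Mutation	2.650527	yes	25, 38
LHCGR	p.E206K	SNP	Missense_Mutation	0.77191	yes	44, 45
MS4A1	p.G115E	SNP	Missense_Mutation	0		52, 79
MTOR	p.A1105T	SNP	Missense_Mutation	0.8908875	yes	65, 66
PDCD1	p.E211K	SNP	Missense_Mutation	0		34, 51
PIK3C2G	p.E1231K	SNP	Missense_Mutation	0		23, 48
PRKCB	p.R361Q	SNP	Missense_Mutation	0.959385		44, 50
ROS1	p.P1539S	SNP	Missense_Mutation	0		20, 26
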