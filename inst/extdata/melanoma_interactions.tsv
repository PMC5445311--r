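gene	drug_or_class	source	antineoplastic
EPHA2	tyrosine kinase inhibitor	TEND	TRUE
GART	folate antimetabolite	TEND	TRUE
KDR	tyrosine kinase inhibitor	TEND	TRUE
KDR	tyrosine kinase inhibitor	MyCancerGenome
KIT	tyrosine kinase inhibitor	TEND	TRUE
KIT	tyrosine kinase inhibitor	MyCancerGenome
LHCGR	GnRH agonist	TEND	TRUE
MS4A1	anti-CD20 antibody	TEND	TRUE
MS4A1	anti-CD20 antibody	MyCancerGenome
MTOR	mTOR inhibitor	TEND	TRUE
MTOR	mTOR inhibitor	MyCancerGenome
PDCD1	anti-PD1 antibody	MyCancerGenome
PIK3C2G	PI3K inhibitor	MyCancerGenome
PRKCB	protein kinase C inhibitor	MyCancerGenome
ROS1	tyrosine kinase inhibitor	MyCancerGenome
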