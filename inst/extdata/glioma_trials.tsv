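gene	agent	combination	trial
BRAF	Dabrafenib	Trametinib, Hydroxycloroquine	NCT04201457
BRAF	Encorafenib	Binimetinib	NCT03973918
BRAF	Dabrafenib	-	NCT02465060
CDK4/CDK6	Abemaciclib	LY3214996	NCT04391595
CDK4/CDK6	Ribociclib	Everolimus	NCT03834740
CDK4/CDK6	Abemaciclib	Bevacizumab	NCT04074785
CDK4/CDK6	Palbociclib	-	NCT02465060
CDK4/CDK6	Palbociclib	-	NCT02530320
EGFR	Afatinib or Osimertinib	-	NCT02465060
KRAS	Ulixertinib	-	NCT04566393
MET	Volitinib	-	NCT03598244
MET	Crizotinib	-	NCT02465060
MET	APL-101	-	NCT03175224
NRAS	Binimetinib	-	NCT02465060
NRAS	Ulixertinib	-	NCT04566393
PIK3CA	Taselisib or Copanlisib	-	NCT02465060
PDGFRA	Crenolanib	-	NCT02626364
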