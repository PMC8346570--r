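patient_id	gene	sample_role	protein_change	effect_class
P01	CTNNB1	LG	p.S45F	missense
P01	CTNNB1	GBC	p.K335T	missense
P03	CTNNB1	GBC	p.T41I	missense
P03	CTNNB1	LG	p.T41I	missense
P03	CTNNB1	HG	p.T41I	missense
P07	CTNNB1	GBC	p.S45F	missense
P07	CTNNB1	LG	p.S45F	missense
P07	CTNNB1	HG	p.S45F	missense
P09	CTNNB1	GBC	p.S33C	missense
P10	CTNNB1	GBC	p.S45F	missense
P10	CTNNB1	LG	p.S45F	missense
P10	CTNNB1	HG	p.S45F	missense
P10	ARID2	GBC	p.Q916*	nonsense
P10	ARID2	LG	p.Q916*	nonsense
P10	ARID2	HG	p.Q916*	nonsense
P02	ARID2	GBC	p.R274C	missense
P05	ARID2	LG	p.E1342K	missense
P08	ARID2	GBC	p.S1456*	nonsense
P11	ARID2	HG	p.Q1573*	nonsense
P02	TP53	GBC	p.R175H	missense
P04	TP53	GBC	p.R273C	missense
P06	TP53	HG	p.R248Q	missense
P10	ERBB3	GBC	p.V104M	missense
P10	ERBB3	LG	p.V104M	missense
P10	ERBB3	HG	p.V104M	missense
P04	ERBB3	LG	p.A232V	missense
P06	ERBB3	LG	p.D297Y	missense
P04	SMARCA4	GBC	p.R1192C	missense
P11	SMARCA4	GBC	p.T910M	missense
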