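signature	etiology
Sig1	aging
Sig2	APOBEC
Sig3	HR_deficiency
Sig4	smoking
Sig5	clock_like
Sig6	MMR_deficiency
Sig7	UV
Sig8	unknown
Sig9	POLH
Sig10	POLE
Sig11	alkylating
Sig12	unknown
Sig13	APOBEC
Sig14	unknown
Sig15	MMR_deficiency
Sig16	unknown
Sig17	unknown
Sig18	unknown
Sig19	unknown
Sig20	MMR_deficiency
Sig21	unknown
Sig22	aristolochic_acid
Sig23	unknown
Sig24	aflatoxin
Sig25	unknown
Sig26	MMR_deficiency
Sig27	unknown
Sig28	unknown
Sig29	tobacco_chewing
Sig30	unknown
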