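patient_id	topology
P01	((LG,HG),GBC)
P02	((GBC,LG),HG)
P03	((GBC,LG),HG)
P04	((LG,HG),GBC)
P05	((GBC,LG),HG)
P06	((LG,HG),GBC)
P07	((GBC,HG),LG)
P08	((LG,HG),GBC)
P09	((LG,HG),GBC)
P10	((GBC,HG),LG)
P11	((LG,HG),GBC)
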