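pathway_id	name	closeness	degree
mcc04660	T cell receptor signaling pathway	0.6	21
mcc04662	B cell receptor signaling pathway	0.59302326	20
mcc04611	Platelet activation	0.46788991	11
mcc04664	Fc epsilon RI signaling pathway	0.49514563	8
mcc04650	Natural killer cell mediated cytotoxicity	0.45945946	7
mcc04062	Chemokine signaling pathway	0.43589744	7
mcc04670	Leukocyte transendothelial migration	0.43220339	5
mcc04621	NOD-like receptor signaling pathway	0.33774834	1
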