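gene	hgvs_c_pattern	hgvs_p_pattern
BRAF	^c\.1799T>A$	V600E|Val600Glu
IDH1		^p\.?(R132|Arg132)
IDH2		^p\.?(R172|Arg172)
TERT	^c\.1-(124|146)C>T$	
H3-3A		K27M|Lys27Met
H3F3A		K27M|Lys27Met
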