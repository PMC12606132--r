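name	accession	mono_mass
Oxidation	UNIMOD:35	15.994915
Carbamidomethyl	UNIMOD:4	57.021464
Acetyl	UNIMOD:1	42.010565
Phospho	UNIMOD:21	79.966331
Gln->pyro-Glu	UNIMOD:28	-17.026549
Glu->pyro-Glu	UNIMOD:27	-18.010565
TMT11	UNIMOD:737	229.162932
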