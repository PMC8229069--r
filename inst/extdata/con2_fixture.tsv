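# CON2 alteration-profile zygosity fixture: 8 columns x 13 samples plus the
# reference consensus row. Cells are zygosity words relative to each
# column's reference allele: hom_ref = reference allele, het = two-base
# ambiguity containing it, hom_alt = alternative allele. Base identities
# are a synthetic convention (only the zygosity structure and the
# match/difference counts are documented facts); column positions within
# the 538-bp fragment are evenly spaced placeholders.
sample	group	c1	c2	c3	c4	c5	c6	c7	c8
reference	0	het	hom_ref	het	het	het	hom_ref	hom_ref	het
Da_KEW-0522816	1	het	het	het	het	het	hom_ref	hom_ref	het
Da_KEW-0661919	1	het	het	het	het	het	hom_ref	hom_ref	het
Da_KEW-0521613	1	het	het	het	het	het	hom_ref	hom_ref	het
Dp_KEW-0661849	1	het	het	het	het	het	hom_ref	hom_ref	het
Ds_78	2	hom_alt	hom_ref	hom_alt	hom_alt	hom_alt	het	het	hom_alt
Dc_PI-562652	2	hom_alt	hom_ref	hom_alt	hom_alt	hom_alt	het	het	hom_alt
Dc_PI-577069	2	hom_alt	hom_ref	hom_alt	hom_alt	hom_alt	het	het	hom_alt
Dc_PI-371724	2	hom_alt	hom_ref	hom_alt	hom_alt	hom_alt	het	het	hom_alt
De_PI-665545	2	hom_alt	hom_ref	hom_alt	hom_alt	hom_alt	het	het	hom_alt
Df_PI-577075	2	hom_alt	hom_ref	hom_alt	hom_alt	hom_alt	het	het	hom_alt
Hp_KEW-065160	3	hom_alt	hom_ref	hom_alt	hom_alt	hom_alt	hom_ref	hom_ref	hom_alt
Km_KEW-0096838	3	hom_alt	hom_ref	hom_alt	hom_alt	hom_alt	hom_ref	hom_ref	hom_alt
Dd_W6-39054	4	hom_alt	hom_ref	hom_alt	hom_alt	hom_alt	het	hom_ref	hom_alt
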