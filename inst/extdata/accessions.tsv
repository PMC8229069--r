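accession_id	species	catalog	origin
Da_KEW-0522816	Deschampsia antarctica	KEW-0522816	Falkland Is., St. Georgia
Da_KEW-0661919	Deschampsia antarctica	KEW-0661919	Falkland Is., Weddle
Da_KEW-0521613	Deschampsia antarctica	KEW-0521613	Falkland Is., St. Georgia
Dc_PI-562652	Deschampsia cespitosa ssp. beringensis	PI-562652	Alaska, USA
Dc_PI-371724	Deschampsia cespitosa	PI-371724	Alaska, Valdez, USA
Dc_PI-577069	Deschampsia cespitosa	PI-577069	Great Britain
Dd_W6-39054	Deschampsia danthonioides	W6-39054	Washington, USA
De_PI-665545	Deschampsia elongata	PI-665545	Oregon, USA
Df_PI-577075	Deschampsia flexuosa	PI-577075	Wales, UK
Dp_KEW-0661849	Deschampsia parvula	KEW-0661849	Falkland Is.
Ds_78	Deschampsia sukatschewii	78	Altai Mountains, RF
Hp_KEW-065160	Helictotrichon pubescens	KEW-065160	England, UK
Km_KEW-0096838	Koeleria macrantha	KEW-0096838	Greece
Tp_KEW-0662385	Trisetum phleoides	KEW-0662385	Falkland Is.
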