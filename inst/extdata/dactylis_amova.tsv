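analysis	stratum	SS	variance_component	proportion	df	p
accessions	among	2132.571	10.892	0.191	19	<0.001
accessions	within	8661.510	46.072	0.809	176	<0.001
hispanica_countries	among	1384.837	11.434	0.108	6	<0.001
hispanica_countries	within	6139.533	94.454	0.892	63	<0.001
lobata_countries	among	165.050	8.970	0.165	2	<0.001
lobata_countries	within	1272.750	45.455	0.835	27	<0.001
smithii_countries	among	144.800	10.340	0.200	2	<0.001
smithii_countries	within	745.200	41.400	0.800	17	<0.001
woronowii_countries	among	141.300	10.508	0.225	2	<0.001
woronowii_countries	within	652.000	36.222	0.775	17	<0.001
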