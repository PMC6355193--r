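section	source	target	weight
brainstem	CnF-Glu	i-PPN-Glu	0.56
brainstem	CnF-Glu	i-LPGi-Glu-1	0.95
brainstem	CnF-Glu	i-LPGi-Glu-2	1.02
brainstem	CnF-Glu	c-CnF-Glu	0.1
brainstem	CnF-Glu	c-PPN-Glu	0.15
brainstem	CnF-Glu	c-LPGi-Glu-1	0.45
brainstem	CnF-Glu	c-LPGi-Glu-2	0.08
brainstem	CnF-GABA/Gly	i-CnF-Glu	-0.5
brainstem	CnF-GABA/Gly	i-PPN-Glu	-0.5
brainstem	PPN-Glu	i-LPGi-Glu-1	1
brainstem	PPN-Glu	c-LPGi-Glu-1	0.4
brainstem	PPN-GABA/Gly	i-PPN-Glu	-0.5
brainstem	LPGi-GABA/Gly	i-LPGi-Glu-1	-0.5
brainstem	LPGi-GABA/Gly	i-LPGi-Glu-2	-0.5
vestibular	VN	i-RG-E	1
brainstem-relay	LPGi-Glu-1	i-Ine	1
brainstem-relay	LPGi-Glu-1	i-CINe	1
brainstem-relay	LPGi-Glu-2	i-dIni	1
brainstem-relay	LPGi-Glu-2	c-dIni	1
brainstem-relay	LPGi-GABA/Gly	c-Ine	-0.5
brainstem-relay	LPGi-GABA/Gly	c-CINe	-0.5
relay-spinal	Ine	i-RG-F	1
relay-spinal	dIni	i-V0_D	4
relay-spinal	dIni	i-V0_V	1.7
relay-spinal	dIni	i-f-V0_D-LPN	7.5
relay-spinal	CINe	c-RG-F	1
within-girdle	RG-F	i-InF	0.4
within-girdle	RG-F	i-V0_D	0.7
within-girdle	RG-F	i-V2a-lr	1
within-girdle	RG-F	i-V3	0.35
within-girdle	RG-F	i-V2a-diag	0.5
within-girdle	f-RG-F	i-LPNi	0.7
within-girdle	f-RG-F	i-V0_D-LPN	0.5
within-girdle	RG-E	i-InE	0.4
within-girdle	RG-E	i-CINi	0.4
within-girdle	RG-E	i-Sh2-LPN	0.5
within-girdle	InF	i-RG-E	-1
within-girdle	InE	i-RG-F	-0.08
within-girdle	V2a-lr	i-V0_V	1
within-girdle	V2a-diag	i-V0_V-LPN	0.9
within-girdle	Ini	i-RG-F	-0.075
left-right	V0_D	c-RG-F	-0.07
left-right	V0_V	c-Ini	0.6
left-right	V3	c-RG-F	0.03
left-right	CINi	c-RG-F	-0.03
fore-hind	f-LPNi	ih-RG-F	-0.01
fore-hind	f-Sh2-LPN	ih-RG-F	0.01
fore-hind	h-Sh2-LPN	if-RG-F	0.075
fore-hind	f-V0_D-LPN	ch-RG-F	-0.1
fore-hind	f-V0_V-LPN	ch-RG-F	0.02
fore-hind	h-V0_V-LPN	cf-RG-F	0.065
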