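class_name	role	gene_symbol
nitrergic	hallmark	NOS1
nitrergic	support	NOS1AP
nitrergic	support	ARG1
nitrergic	support	ARG2
nitrergic	support	ASL
nitrergic	support	ASS1
cholinergic	hallmark	CHAT
cholinergic	support	SLC5A7
cholinergic	support	SLC18A3
cholinergic	support	ACHE
glutamatergic	hallmark	GLS
glutamatergic	support	SLC17A6
glutamatergic	support	SLC17A7
glutamatergic	support	GLUL
catecholaminergic	hallmark	TH
catecholaminergic	support	DDC
catecholaminergic	support	DBH
catecholaminergic	support	SLC18A2
GABAergic	hallmark	GAD1
GABAergic	hallmark	GAD2
GABAergic	support	SLC32A1
GABAergic	support	ABAT
GABAergic	support	SLC6A1
serotonergic	hallmark	TPH2
serotonergic	support	SLC6A4
serotonergic	support	SLC18A1
serotonergic	support	MAOA
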