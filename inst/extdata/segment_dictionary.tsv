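kind	key	synonym
artery	lm	left main coronary artery
artery	lm	left main
artery	lm	LMCA
artery	lm	LM
artery	lad	left anterior descending artery
artery	lad	left anterior descending
artery	lad	LAD
artery	lcx	left circumflex artery
artery	lcx	left circumflex
artery	lcx	circumflex artery
artery	lcx	circumflex
artery	lcx	LCX
artery	rca	right coronary artery
artery	rca	right coronary
artery	rca	RCA
artery	pda	posterior descending artery
artery	pda	posterior descending
artery	pda	PDA
position	ostial	ostial
position	ostial	ostium
position	prox	proximal
position	prox	proximally
position	prox	prox
position	mid	middle
position	mid	mid
position	dist	distal
position	dist	distally
excluded	excluded	diagonal
excluded	excluded	D1
excluded	excluded	D2
excluded	excluded	obtuse marginal
excluded	excluded	marginal
excluded	excluded	OM1
excluded	excluded	OM2
excluded	excluded	OM
excluded	excluded	ramus
excluded	excluded	septal
excluded	excluded	bypass graft
excluded	excluded	graft
excluded	excluded	SVG
excluded	excluded	LIMA
excluded	excluded	RIMA
excluded	excluded	posterolateral
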