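subfamily	column	residue
DREB	3	W
DREB	7	G
DREB	11	Q
DREB	15	E
DREB	19	E
DREB	23	H
DREB	27	L
DREB	31	W
DREB	35	Y
DREB	39	Y
DREB	43	C
DREB	47	F
DREB	51	V
DREB	55	M
DRF	5	R
DRF	9	Y
DRF	13	T
DRF	17	V
DRF	21	G
DRF	25	H
DRF	29	T
DRF	33	Q
DRF	37	A
DRF	41	Q
DRF	45	H
DRF	49	W
DRF	53	W
DRF	57	L
SOLOIST	2	V
SOLOIST	7	L
SOLOIST	9	E
SOLOIST	12	W
SOLOIST	16	I
SOLOIST	17	C
SOLOIST	19	K
SOLOIST	21	L
SOLOIST	22	K
SOLOIST	23	E
SOLOIST	24	R
SOLOIST	35	L
SOLOIST	42	A
SOLOIST	45	Y
SOLOIST	46	M
SOLOIST	47	G
SOLOIST	49	N
SOLOIST	51	R
SOLOIST	52	D
SOLOIST	55	C
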