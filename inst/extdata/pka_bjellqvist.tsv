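role	key	pka
positive	Nterm_default	7.5
positive	K	10.0
positive	R	12.0
positive	H	5.98
negative	Cterm_default	3.55
negative	D	4.05
negative	E	4.45
negative	C	9.0
negative	Y	10.0
nterm	A	7.59
nterm	M	7.0
nterm	S	6.93
nterm	P	8.36
nterm	T	6.82
nterm	V	7.44
nterm	E	7.7
cterm	D	4.55
cterm	E	4.75
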