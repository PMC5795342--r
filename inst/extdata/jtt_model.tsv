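aa_i	aa_j	rate
R	A	58
N	A	54
D	A	81
C	A	56
Q	A	57
E	A	105
G	A	179
H	A	27
I	A	36
L	A	30
K	A	35
M	A	54
F	A	15
P	A	194
S	A	378
T	A	475
W	A	9
Y	A	11
V	A	298
N	R	45
D	R	16
C	R	113
Q	R	310
E	R	29
G	R	137
H	R	328
I	R	22
L	R	38
K	R	646
M	R	44
F	R	5
P	R	74
S	R	101
T	R	64
W	R	126
Y	R	20
V	R	17
D	N	528
C	N	34
Q	N	86
E	N	58
G	N	81
H	N	391
I	N	47
L	N	12
K	N	263
M	N	30
F	N	10
P	N	15
S	N	503
T	N	232
W	N	8
Y	N	70
V	N	16
C	D	10
Q	D	49
E	D	767
G	D	130
H	D	112
I	D	11
L	D	7
K	D	26
M	D	15
F	D	4
P	D	15
S	D	59
T	D	38
W	D	4
Y	D	46
V	D	31
Q	C	9
E	C	5
G	C	59
H	C	69
I	C	17
L	C	23
K	C	7
M	C	31
F	C	78
P	C	14
S	C	223
T	C	42
W	C	115
Y	C	209
V	C	62
E	Q	323
G	Q	26
H	Q	597
I	Q	9
L	Q	72
K	Q	292
M	Q	43
F	Q	4
P	Q	164
S	Q	53
T	Q	51
W	Q	18
Y	Q	24
V	Q	20
G	E	119
H	E	26
I	E	12
L	E	9
K	E	181
M	E	18
F	E	5
P	E	18
S	E	30
T	E	32
W	E	10
Y	E	7
V	E	45
H	G	23
I	G	6
L	G	6
K	G	27
M	G	14
F	G	5
P	G	24
S	G	201
T	G	33
W	G	55
Y	G	8
V	G	47
I	H	16
L	H	56
K	H	45
M	H	33
F	H	40
P	H	115
S	H	73
T	H	46
W	H	8
Y	H	573
V	H	11
L	I	229
K	I	21
M	I	479
F	I	89
P	I	10
S	I	40
T	I	245
W	I	9
Y	I	32
V	I	961
K	L	14
M	L	388
F	L	248
P	L	102
S	L	59
T	L	25
W	L	52
Y	L	24
V	L	180
M	K	65
F	K	4
P	K	21
S	K	47
T	K	103
W	K	10
Y	K	8
V	K	14
F	M	43
P	M	16
S	M	29
T	M	226
W	M	24
Y	M	18
V	M	323
P	F	17
S	F	92
T	F	12
W	F	53
Y	F	536
V	F	62
S	P	285
T	P	118
W	P	6
Y	P	10
V	P	23
T	S	477
W	S	35
Y	S	63
V	S	38
W	T	12
Y	T	21
V	T	112
Y	W	71
V	W	25
V	Y	16
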