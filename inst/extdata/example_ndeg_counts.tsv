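#hybrid	tissue	up	down
H1xH8	0-L	62	17
H1xH8	0-S	40	15
H1xH8	0-P	48	56
H1xH8	0-Z	86	23
H1xH8	5-L	20	4
H1xH8	5-S	86	93
H1xH8	5-P	100	80
H1xH8	5-Z	47	65
T485xH8	0-L	21	27
T485xH8	0-S	41	20
T485xH8	0-P	32	7
T485xH8	0-Z	58	19
T485xH8	5-L	7	8
T485xH8	5-S	32	35
T485xH8	5-P	63	130
T485xH8	5-Z	23	28
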