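#hybrid	tissue	deg2p	degp1	degp2	degfu_sp
H1xH8	0-L	6257	1465	4874	1162
H1xH8	0-S	4716	1342	3730	1408
H1xH8	0-P	2409	1534	2205	1548
H1xH8	0-Z	3615	995	2745	1151
H1xH8	5-L	2120	1131	857	521
H1xH8	5-S	4503	3813	3972	3020
H1xH8	5-P	8489	984	6049	1137
H1xH8	5-Z	3602	1665	3854	1903
T485xH8	0-L	6374	5082	1785	1568
T485xH8	0-S	6309	4131	1485	1232
T485xH8	0-P	3173	1539	1696	961
T485xH8	0-Z	4872	1849	3707	1591
T485xH8	5-L	2471	1506	1046	762
T485xH8	5-S	3328	1358	2605	1390
T485xH8	5-P	3882	2902	4320	3141
T485xH8	5-Z	3364	1603	3064	1550
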