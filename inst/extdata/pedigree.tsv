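proband	father	mother
01	.	.
02	.	.
03	.	.
04	.	.
05	.	.
06	.	.
07	.	.
08	.	.
09	.	.
10	.	.
11	.	.
12	.	.
13	.	.
14	14_F	14_M
15	15_F	15_M
16	16_F	16_M
17	17_F	17_M
18	18_F	18_M
19	19_F	19_M
20	20_F	20_M
21	21_F	21_M
22	22_F	22_M
23	23_F	23_M
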