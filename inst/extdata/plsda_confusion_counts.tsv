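observed	URI	DOA	DMB	GST	FML	MSC	PIN	RSP	WND
URI	39	0	0	21	2	10	0	0	0
DOA	0	164	0	29	36	18	0	0	2
DMB	0	1	5	10	0	3	1	2	0
GST	3	17	0	880	12	46	9	6	7
FML	0	13	0	61	266	50	5	1	2
MSC	6	6	1	127	41	638	16	0	5
PIN	1	0	0	90	4	77	133	4	2
RSP	3	0	0	21	4	23	3	52	1
WND	2	3	0	57	11	11	4	0	71
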