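# Stable isotope masses (Da) and natural abundances (fraction)
element	nucleons	mass	abundance
H	1	1.0078250319	0.999885
H	2	2.0141017781	0.000115
C	12	12.0	0.9893
C	13	13.0033548351	0.0107
N	14	14.0030740052	0.99636
N	15	15.0001088989	0.00364
O	16	15.9949146221	0.99757
O	17	16.9991315	0.00038
O	18	17.9991604	0.00205
S	32	31.97207069	0.9499
S	33	32.9714585	0.0075
S	34	33.96786683	0.0425
S	36	35.96708088	0.0001
P	31	30.97376151	1.0
Na	23	22.98976928	1.0
K	39	38.96370649	0.932581
K	40	39.96399817	0.000117
K	41	40.96182526	0.067302
Fe	54	53.93960899	0.05845
Fe	56	55.93493633	0.91754
Fe	57	56.93539284	0.02119
Fe	58	57.93327443	0.00282
Cu	63	62.92959772	0.6915
Cu	65	64.9277897	0.3085
Zn	64	63.92914201	0.4917
Zn	66	65.92603381	0.2773
Zn	67	66.92712775	0.0404
Zn	68	67.92484455	0.1845
Zn	70	69.9253192	0.0061
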