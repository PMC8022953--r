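lineage	region	recipient	changed_positions	donors	min_start	min_end	max_start	max_end
L4	16S	rrnD	210	rrnC,rrnE,rrnG	210	210	1	1001
L1	16S	rrnB	497	rrnA,rrnH	497	497	320	905
L2	16S	rrnC	684,1021	rrnA	684	1021	497	1390
L6	16S	rrnA	1390	rrnB,rrnD	1390	1390	1022	1542
L8	16S	rrnH	210	rrnC,rrnE,rrnG	210	210	1	496
L11	16S	rrnC	1021	rrnB	1021	1021	685	1389
L14	16S	rrnB	684	rrnD,rrnE	684	684	498	1020
L1	23S	rrnC	1317,1322	rrnA	1317	1322	739	1856
L2	23S	rrnC	1331	rrnB	1331	1331	1025	1855
L3	23S	rrnC	1322,1331,1340	rrnA	1322	1340	1318	2102
L5	23S	rrnC	412	rrnB	412	412	188	738
L6	23S	rrnC	1340	rrnB	1340	1340	1332	2102
L8	23S	rrnC	1340,1856	rrnA	1340	1856	1332	2239
L9	23S	rrnC	1317	rrnB	1317	1317	1025	1321
L12	23S	rrnC	739,1024	rrnB	739	1024	413	1316
L15	23S	rrnC	2103,2240	rrnD	2103	2240	1857	2435
L2	23S	rrnB	1317,1322,1331	rrnA	1317	1331	740	1339
L4	23S	rrnB	187	rrnE,rrnH	187	187	1	411
L5	23S	rrnB	1340	rrnC,rrnE	1340	1340	1025	1855
L7	23S	rrnB	1024	rrnD	1024	1024	740	1316
L10	23S	rrnB	1322	rrnA	1322	1322	1318	1330
L11	23S	rrnB	300,412,739,1024,1317,1322,1331,1340,1856,2436	rrnE	300	2436	188	2500
L13	23S	rrnB	1856	rrnA,rrnG	1856	1856	1341	2102
L3	23S	rrnA	1331,1340	rrnC	1331	1340	1323	1855
L9	23S	rrnA	739	rrnB,rrnD	739	739	413	1023
L14	23S	rrnA	1317	rrnG	1317	1317	1025	1321
L1	23S	rrnD	2436	rrnB,rrnH	2436	2436	2241	2904
L7	23S	rrnD	1322,1331	rrnB	1322	1331	1318	1339
L12	23S	rrnD	187	rrnC	187	187	1	411
L6	23S	rrnE	1024	rrnA,rrnB	1024	1024	740	1316
L10	23S	rrnE	1340,1856	rrnC	1340	1856	1332	2102
L13	23S	rrnE	2103	rrnH	2103	2103	1857	2239
L8	23S	rrnH	1317,1322	rrnB	1317	1322	740	1330
L15	23S	rrnH	412	rrnD,rrnE	412	412	188	738
L2	spacer	rrnD	1	rrnB,rrnC,rrnG	1	186	1	186
L5	spacer	rrnB	1	rrnA,rrnD,rrnE,rrnH	1	186	1	186
L9	spacer	rrnG	1	rrnA,rrnD,rrnE,rrnH	1	186	1	186
L13	spacer	rrnC	1	rrnA,rrnD,rrnE,rrnH	1	186	1	186
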