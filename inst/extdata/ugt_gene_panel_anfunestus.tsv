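gene_id	chrom	start	end	strand	printed_length_bp
UGT301A3	2	82046643	82050536	+	3893
UGT301C2	2	82055953	82057683	+	1730
UGT301E3	2	82044343	82046282	+	1939
UGT302A3	3	24375218	24377273	-	2055
UGT302H3	3	18529610	18531839	-	2229
UGT302J2	3	18532418	18535025	+	2607
UGT306A3	3	383756	385945	-	2189
UGT306C2	3	381521	383356	-	1835
UGT306D2	3	91183810	91186351	-	2541
UGT308A3	3	19909980	19911965	+	1985
UGT308B3	3	19912087	19916060	+	3973
UGT308C3	3	19907113	19909550	-	2437
UGT308D2	3	10785724	10787606	+	1882
UGT308F2	3	19904812	19907016	+	2204
UGT308G2	2	88001139	88003007	+	1868
UGT308G3	2	87998349	88000579	+	2230
UGT308G4	2	87995100	87997861	+	2761
UGT308H2	3	19912087	19916060	+	3973
UGT309B2	3	59521361	59523238	-	1877
UGT310B2	2	38876258	38878428	-	2170
UGT313B2	2	73697488	73703548	+	6060
UGT314A3	2	37732412	37740072	+	7660
UGT315A3	3	40270911	40273123	+	2212
UGT36B3	2	90789423	90801509	-	12086
UGT36C3	2	90804657	90812858	-	8201
UGT49A4	3	3257425	3259981	+	2556
UGT50B8	2	16896116	16933648	+	37532
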