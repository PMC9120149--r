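##gff-version 3
sp01_fam1_og1	paralintron_sim	mRNA	21	907	.	+	.	ID=sp01|fam1_og1|t1
sp01_fam1_og1	paralintron_sim	CDS	21	58	.	+	0	ID=sp01|fam1_og1|t1.cds;Parent=sp01|fam1_og1|t1;protein_id=sp01|fam1_og1
sp01_fam1_og1	paralintron_sim	CDS	131	134	.	+	1	ID=sp01|fam1_og1|t1.cds;Parent=sp01|fam1_og1|t1;protein_id=sp01|fam1_og1
sp01_fam1_og1	paralintron_sim	CDS	219	226	.	+	0	ID=sp01|fam1_og1|t1.cds;Parent=sp01|fam1_og1|t1;protein_id=sp01|fam1_og1
sp01_fam1_og1	paralintron_sim	CDS	292	297	.	+	1	ID=sp01|fam1_og1|t1.cds;Parent=sp01|fam1_og1|t1;protein_id=sp01|fam1_og1
sp01_fam1_og1	paralintron_sim	CDS	358	361	.	+	1	ID=sp01|fam1_og1|t1.cds;Parent=sp01|fam1_og1|t1;protein_id=sp01|fam1_og1
sp01_fam1_og1	paralintron_sim	CDS	432	444	.	+	0	ID=sp01|fam1_og1|t1.cds;Parent=sp01|fam1_og1|t1;protein_id=sp01|fam1_og1
sp01_fam1_og1	paralintron_sim	CDS	520	557	.	+	2	ID=sp01|fam1_og1|t1.cds;Parent=sp01|fam1_og1|t1;protein_id=sp01|fam1_og1
sp01_fam1_og1	paralintron_sim	CDS	677	735	.	+	0	ID=sp01|fam1_og1|t1.cds;Parent=sp01|fam1_og1|t1;protein_id=sp01|fam1_og1
sp01_fam1_og1	paralintron_sim	CDS	797	800	.	+	1	ID=sp01|fam1_og1|t1.cds;Parent=sp01|fam1_og1|t1;protein_id=sp01|fam1_og1
sp01_fam1_og1	paralintron_sim	CDS	899	907	.	+	0	ID=sp01|fam1_og1|t1.cds;Parent=sp01|fam1_og1|t1;protein_id=sp01|fam1_og1
sp01_fam1_og2	paralintron_sim	mRNA	21	813	.	-	.	ID=sp01|fam1_og2|t1
sp01_fam1_og2	paralintron_sim	CDS	21	29	.	-	0	ID=sp01|fam1_og2|t1.cds;Parent=sp01|fam1_og2|t1;protein_id=sp01|fam1_og2
sp01_fam1_og2	paralintron_sim	CDS	104	106	.	-	0	ID=sp01|fam1_og2|t1.cds;Parent=sp01|fam1_og2|t1;protein_id=sp01|fam1_og2
sp01_fam1_og2	paralintron_sim	CDS	201	201	.	-	1	ID=sp01|fam1_og2|t1.cds;Parent=sp01|fam1_og2|t1;protein_id=sp01|fam1_og2
sp01_fam1_og2	paralintron_sim	CDS	268	287	.	-	0	ID=sp01|fam1_og2|t1.cds;Parent=sp01|fam1_og2|t1;protein_id=sp01|fam1_og2
sp01_fam1_og2	paralintron_sim	CDS	370	406	.	-	1	ID=sp01|fam1_og2|t1.cds;Parent=sp01|fam1_og2|t1;protein_id=sp01|fam1_og2
sp01_fam1_og2	paralintron_sim	CDS	519	583	.	-	0	ID=sp01|fam1_og2|t1.cds;Parent=sp01|fam1_og2|t1;protein_id=sp01|fam1_og2
sp01_fam1_og2	paralintron_sim	CDS	662	668	.	-	1	ID=sp01|fam1_og2|t1.cds;Parent=sp01|fam1_og2|t1;protein_id=sp01|fam1_og2
sp01_fam1_og2	paralintron_sim	CDS	773	813	.	-	0	ID=sp01|fam1_og2|t1.cds;Parent=sp01|fam1_og2|t1;protein_id=sp01|fam1_og2
sp01_fam2_og1	paralintron_sim	mRNA	21	736	.	-	.	ID=sp01|fam2_og1|t1
sp01_fam2_og1	paralintron_sim	CDS	21	91	.	-	2	ID=sp01|fam2_og1|t1.cds;Parent=sp01|fam2_og1|t1;protein_id=sp01|fam2_og1
sp01_fam2_og1	paralintron_sim	CDS	211	246	.	-	2	ID=sp01|fam2_og1|t1.cds;Parent=sp01|fam2_og1|t1;protein_id=sp01|fam2_og1
sp01_fam2_og1	paralintron_sim	CDS	353	381	.	-	1	ID=sp01|fam2_og1|t1.cds;Parent=sp01|fam2_og1|t1;protein_id=sp01|fam2_og1
sp01_fam2_og1	paralintron_sim	CDS	492	500	.	-	1	ID=sp01|fam2_og1|t1.cds;Parent=sp01|fam2_og1|t1;protein_id=sp01|fam2_og1
sp01_fam2_og1	paralintron_sim	CDS	593	603	.	-	0	ID=sp01|fam2_og1|t1.cds;Parent=sp01|fam2_og1|t1;protein_id=sp01|fam2_og1
sp01_fam2_og1	paralintron_sim	CDS	710	736	.	-	0	ID=sp01|fam2_og1|t1.cds;Parent=sp01|fam2_og1|t1;protein_id=sp01|fam2_og1
sp01_fam2_og2	paralintron_sim	mRNA	21	832	.	+	.	ID=sp01|fam2_og2|t1
sp01_fam2_og2	paralintron_sim	CDS	21	67	.	+	0	ID=sp01|fam2_og2|t1.cds;Parent=sp01|fam2_og2|t1;protein_id=sp01|fam2_og2
sp01_fam2_og2	paralintron_sim	CDS	146	155	.	+	1	ID=sp01|fam2_og2|t1.cds;Parent=sp01|fam2_og2|t1;protein_id=sp01|fam2_og2
sp01_fam2_og2	paralintron_sim	CDS	268	280	.	+	0	ID=sp01|fam2_og2|t1.cds;Parent=sp01|fam2_og2|t1;protein_id=sp01|fam2_og2
sp01_fam2_og2	paralintron_sim	CDS	362	364	.	+	2	ID=sp01|fam2_og2|t1.cds;Parent=sp01|fam2_og2|t1;protein_id=sp01|fam2_og2
sp01_fam2_og2	paralintron_sim	CDS	435	437	.	+	2	ID=sp01|fam2_og2|t1.cds;Parent=sp01|fam2_og2|t1;protein_id=sp01|fam2_og2
sp01_fam2_og2	paralintron_sim	CDS	518	583	.	+	2	ID=sp01|fam2_og2|t1.cds;Parent=sp01|fam2_og2|t1;protein_id=sp01|fam2_og2
sp01_fam2_og2	paralintron_sim	CDS	682	699	.	+	2	ID=sp01|fam2_og2|t1.cds;Parent=sp01|fam2_og2|t1;protein_id=sp01|fam2_og2
sp01_fam2_og2	paralintron_sim	CDS	810	832	.	+	2	ID=sp01|fam2_og2|t1.cds;Parent=sp01|fam2_og2|t1;protein_id=sp01|fam2_og2
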