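##gff-version 3
sp02_fam1_og1	paralintron_sim	mRNA	21	1026	.	+	.	ID=sp02|fam1_og1|t1
sp02_fam1_og1	paralintron_sim	CDS	21	62	.	+	0	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og1	paralintron_sim	CDS	164	171	.	+	0	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og1	paralintron_sim	CDS	270	275	.	+	1	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og1	paralintron_sim	CDS	360	363	.	+	1	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og1	paralintron_sim	CDS	437	449	.	+	0	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og1	paralintron_sim	CDS	538	571	.	+	2	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og1	paralintron_sim	CDS	640	643	.	+	1	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og1	paralintron_sim	CDS	713	769	.	+	0	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og1	paralintron_sim	CDS	857	858	.	+	0	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og1	paralintron_sim	CDS	944	947	.	+	1	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og1	paralintron_sim	CDS	1018	1026	.	+	0	ID=sp02|fam1_og1|t1.cds;Parent=sp02|fam1_og1|t1;protein_id=sp02|fam1_og1
sp02_fam1_og2	paralintron_sim	mRNA	21	888	.	-	.	ID=sp02|fam1_og2|t1
sp02_fam1_og2	paralintron_sim	CDS	21	32	.	-	0	ID=sp02|fam1_og2|t1.cds;Parent=sp02|fam1_og2|t1;protein_id=sp02|fam1_og2
sp02_fam1_og2	paralintron_sim	CDS	147	147	.	-	1	ID=sp02|fam1_og2|t1.cds;Parent=sp02|fam1_og2|t1;protein_id=sp02|fam1_og2
sp02_fam1_og2	paralintron_sim	CDS	229	248	.	-	0	ID=sp02|fam1_og2|t1.cds;Parent=sp02|fam1_og2|t1;protein_id=sp02|fam1_og2
sp02_fam1_og2	paralintron_sim	CDS	316	352	.	-	1	ID=sp02|fam1_og2|t1.cds;Parent=sp02|fam1_og2|t1;protein_id=sp02|fam1_og2
sp02_fam1_og2	paralintron_sim	CDS	429	464	.	-	1	ID=sp02|fam1_og2|t1.cds;Parent=sp02|fam1_og2|t1;protein_id=sp02|fam1_og2
sp02_fam1_og2	paralintron_sim	CDS	558	579	.	-	2	ID=sp02|fam1_og2|t1.cds;Parent=sp02|fam1_og2|t1;protein_id=sp02|fam1_og2
sp02_fam1_og2	paralintron_sim	CDS	676	685	.	-	0	ID=sp02|fam1_og2|t1.cds;Parent=sp02|fam1_og2|t1;protein_id=sp02|fam1_og2
sp02_fam1_og2	paralintron_sim	CDS	759	762	.	-	1	ID=sp02|fam1_og2|t1.cds;Parent=sp02|fam1_og2|t1;protein_id=sp02|fam1_og2
sp02_fam1_og2	paralintron_sim	CDS	848	888	.	-	0	ID=sp02|fam1_og2|t1.cds;Parent=sp02|fam1_og2|t1;protein_id=sp02|fam1_og2
sp02_fam2_og1	paralintron_sim	mRNA	21	723	.	+	.	ID=sp02|fam2_og1|t1
sp02_fam2_og1	paralintron_sim	CDS	21	47	.	+	0	ID=sp02|fam2_og1|t1.cds;Parent=sp02|fam2_og1|t1;protein_id=sp02|fam2_og1
sp02_fam2_og1	paralintron_sim	CDS	163	173	.	+	0	ID=sp02|fam2_og1|t1.cds;Parent=sp02|fam2_og1|t1;protein_id=sp02|fam2_og1
sp02_fam2_og1	paralintron_sim	CDS	267	275	.	+	1	ID=sp02|fam2_og1|t1.cds;Parent=sp02|fam2_og1|t1;protein_id=sp02|fam2_og1
sp02_fam2_og1	paralintron_sim	CDS	390	418	.	+	1	ID=sp02|fam2_og1|t1.cds;Parent=sp02|fam2_og1|t1;protein_id=sp02|fam2_og1
sp02_fam2_og1	paralintron_sim	CDS	533	568	.	+	2	ID=sp02|fam2_og1|t1.cds;Parent=sp02|fam2_og1|t1;protein_id=sp02|fam2_og1
sp02_fam2_og1	paralintron_sim	CDS	653	723	.	+	2	ID=sp02|fam2_og1|t1.cds;Parent=sp02|fam2_og1|t1;protein_id=sp02|fam2_og1
sp02_fam2_og2	paralintron_sim	mRNA	21	676	.	-	.	ID=sp02|fam2_og2|t1
sp02_fam2_og2	paralintron_sim	CDS	21	43	.	-	2	ID=sp02|fam2_og2|t1.cds;Parent=sp02|fam2_og2|t1;protein_id=sp02|fam2_og2
sp02_fam2_og2	paralintron_sim	CDS	153	242	.	-	2	ID=sp02|fam2_og2|t1.cds;Parent=sp02|fam2_og2|t1;protein_id=sp02|fam2_og2
sp02_fam2_og2	paralintron_sim	CDS	323	335	.	-	0	ID=sp02|fam2_og2|t1.cds;Parent=sp02|fam2_og2|t1;protein_id=sp02|fam2_og2
sp02_fam2_og2	paralintron_sim	CDS	426	435	.	-	1	ID=sp02|fam2_og2|t1.cds;Parent=sp02|fam2_og2|t1;protein_id=sp02|fam2_og2
sp02_fam2_og2	paralintron_sim	CDS	548	567	.	-	0	ID=sp02|fam2_og2|t1.cds;Parent=sp02|fam2_og2|t1;protein_id=sp02|fam2_og2
sp02_fam2_og2	paralintron_sim	CDS	650	676	.	-	0	ID=sp02|fam2_og2|t1.cds;Parent=sp02|fam2_og2|t1;protein_id=sp02|fam2_og2
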