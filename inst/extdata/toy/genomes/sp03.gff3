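##gff-version 3
sp03_fam1_og1	paralintron_sim	mRNA	21	1098	.	-	.	ID=sp03|fam1_og1|t1
sp03_fam1_og1	paralintron_sim	CDS	21	29	.	-	0	ID=sp03|fam1_og1|t1.cds;Parent=sp03|fam1_og1|t1;protein_id=sp03|fam1_og1
sp03_fam1_og1	paralintron_sim	CDS	113	118	.	-	0	ID=sp03|fam1_og1|t1.cds;Parent=sp03|fam1_og1|t1;protein_id=sp03|fam1_og1
sp03_fam1_og1	paralintron_sim	CDS	221	265	.	-	0	ID=sp03|fam1_og1|t1.cds;Parent=sp03|fam1_og1|t1;protein_id=sp03|fam1_og1
sp03_fam1_og1	paralintron_sim	CDS	359	370	.	-	0	ID=sp03|fam1_og1|t1.cds;Parent=sp03|fam1_og1|t1;protein_id=sp03|fam1_og1
sp03_fam1_og1	paralintron_sim	CDS	491	494	.	-	1	ID=sp03|fam1_og1|t1.cds;Parent=sp03|fam1_og1|t1;protein_id=sp03|fam1_og1
sp03_fam1_og1	paralintron_sim	CDS	612	658	.	-	0	ID=sp03|fam1_og1|t1.cds;Parent=sp03|fam1_og1|t1;protein_id=sp03|fam1_og1
sp03_fam1_og1	paralintron_sim	CDS	722	725	.	-	1	ID=sp03|fam1_og1|t1.cds;Parent=sp03|fam1_og1|t1;protein_id=sp03|fam1_og1
sp03_fam1_og1	paralintron_sim	CDS	846	851	.	-	1	ID=sp03|fam1_og1|t1.cds;Parent=sp03|fam1_og1|t1;protein_id=sp03|fam1_og1
sp03_fam1_og1	paralintron_sim	CDS	951	958	.	-	0	ID=sp03|fam1_og1|t1.cds;Parent=sp03|fam1_og1|t1;protein_id=sp03|fam1_og1
sp03_fam1_og1	paralintron_sim	CDS	1057	1098	.	-	0	ID=sp03|fam1_og1|t1.cds;Parent=sp03|fam1_og1|t1;protein_id=sp03|fam1_og1
sp03_fam1_og2	paralintron_sim	mRNA	21	945	.	+	.	ID=sp03|fam1_og2|t1
sp03_fam1_og2	paralintron_sim	CDS	21	47	.	+	0	ID=sp03|fam1_og2|t1.cds;Parent=sp03|fam1_og2|t1;protein_id=sp03|fam1_og2
sp03_fam1_og2	paralintron_sim	CDS	122	135	.	+	0	ID=sp03|fam1_og2|t1.cds;Parent=sp03|fam1_og2|t1;protein_id=sp03|fam1_og2
sp03_fam1_og2	paralintron_sim	CDS	237	240	.	+	1	ID=sp03|fam1_og2|t1.cds;Parent=sp03|fam1_og2|t1;protein_id=sp03|fam1_og2
sp03_fam1_og2	paralintron_sim	CDS	353	355	.	+	0	ID=sp03|fam1_og2|t1.cds;Parent=sp03|fam1_og2|t1;protein_id=sp03|fam1_og2
sp03_fam1_og2	paralintron_sim	CDS	430	436	.	+	0	ID=sp03|fam1_og2|t1.cds;Parent=sp03|fam1_og2|t1;protein_id=sp03|fam1_og2
sp03_fam1_og2	paralintron_sim	CDS	539	596	.	+	2	ID=sp03|fam1_og2|t1.cds;Parent=sp03|fam1_og2|t1;protein_id=sp03|fam1_og2
sp03_fam1_og2	paralintron_sim	CDS	712	748	.	+	1	ID=sp03|fam1_og2|t1.cds;Parent=sp03|fam1_og2|t1;protein_id=sp03|fam1_og2
sp03_fam1_og2	paralintron_sim	CDS	848	868	.	+	0	ID=sp03|fam1_og2|t1.cds;Parent=sp03|fam1_og2|t1;protein_id=sp03|fam1_og2
sp03_fam1_og2	paralintron_sim	CDS	934	945	.	+	0	ID=sp03|fam1_og2|t1.cds;Parent=sp03|fam1_og2|t1;protein_id=sp03|fam1_og2
sp03_fam2_og1	paralintron_sim	mRNA	21	592	.	-	.	ID=sp03|fam2_og1|t1
sp03_fam2_og1	paralintron_sim	CDS	21	91	.	-	2	ID=sp03|fam2_og1|t1.cds;Parent=sp03|fam2_og1|t1;protein_id=sp03|fam2_og1
sp03_fam2_og1	paralintron_sim	CDS	153	188	.	-	2	ID=sp03|fam2_og1|t1.cds;Parent=sp03|fam2_og1|t1;protein_id=sp03|fam2_og1
sp03_fam2_og1	paralintron_sim	CDS	253	281	.	-	1	ID=sp03|fam2_og1|t1.cds;Parent=sp03|fam2_og1|t1;protein_id=sp03|fam2_og1
sp03_fam2_og1	paralintron_sim	CDS	360	367	.	-	0	ID=sp03|fam2_og1|t1.cds;Parent=sp03|fam2_og1|t1;protein_id=sp03|fam2_og1
sp03_fam2_og1	paralintron_sim	CDS	461	472	.	-	0	ID=sp03|fam2_og1|t1.cds;Parent=sp03|fam2_og1|t1;protein_id=sp03|fam2_og1
sp03_fam2_og1	paralintron_sim	CDS	566	592	.	-	0	ID=sp03|fam2_og1|t1.cds;Parent=sp03|fam2_og1|t1;protein_id=sp03|fam2_og1
sp03_fam2_og2	paralintron_sim	mRNA	21	970	.	-	.	ID=sp03|fam2_og2|t1
sp03_fam2_og2	paralintron_sim	CDS	21	38	.	-	0	ID=sp03|fam2_og2|t1.cds;Parent=sp03|fam2_og2|t1;protein_id=sp03|fam2_og2
sp03_fam2_og2	paralintron_sim	CDS	149	153	.	-	2	ID=sp03|fam2_og2|t1.cds;Parent=sp03|fam2_og2|t1;protein_id=sp03|fam2_og2
sp03_fam2_og2	paralintron_sim	CDS	263	280	.	-	2	ID=sp03|fam2_og2|t1.cds;Parent=sp03|fam2_og2|t1;protein_id=sp03|fam2_og2
sp03_fam2_og2	paralintron_sim	CDS	358	387	.	-	2	ID=sp03|fam2_og2|t1.cds;Parent=sp03|fam2_og2|t1;protein_id=sp03|fam2_og2
sp03_fam2_og2	paralintron_sim	CDS	448	483	.	-	2	ID=sp03|fam2_og2|t1.cds;Parent=sp03|fam2_og2|t1;protein_id=sp03|fam2_og2
sp03_fam2_og2	paralintron_sim	CDS	559	564	.	-	2	ID=sp03|fam2_og2|t1.cds;Parent=sp03|fam2_og2|t1;protein_id=sp03|fam2_og2
sp03_fam2_og2	paralintron_sim	CDS	643	655	.	-	0	ID=sp03|fam2_og2|t1.cds;Parent=sp03|fam2_og2|t1;protein_id=sp03|fam2_og2
sp03_fam2_og2	paralintron_sim	CDS	755	764	.	-	1	ID=sp03|fam2_og2|t1.cds;Parent=sp03|fam2_og2|t1;protein_id=sp03|fam2_og2
sp03_fam2_og2	paralintron_sim	CDS	825	832	.	-	0	ID=sp03|fam2_og2|t1.cds;Parent=sp03|fam2_og2|t1;protein_id=sp03|fam2_og2
sp03_fam2_og2	paralintron_sim	CDS	932	970	.	-	0	ID=sp03|fam2_og2|t1.cds;Parent=sp03|fam2_og2|t1;protein_id=sp03|fam2_og2
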