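og_id	family_id	acquisition_id	ambiguous
fam1_og1	fam1	fam1_acq1	FALSE
fam1_og2	fam1	fam1_acq1	FALSE
fam2_og1	fam2	fam2_acq1	FALSE
fam2_og2	fam2	fam2_acq1	FALSE
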