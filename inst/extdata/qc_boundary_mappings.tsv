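transcript_id	gene_id	coding_length	coverage_fraction	lowqual_fraction	indels	in_frame_stop	splice_sites_conserved
t01_clean_boundaries	g01	300	0.80	0.10	.	FALSE	TRUE
t02_low_coverage	g02	300	0.79	0.00	.	FALSE	TRUE
t03_high_lowqual	g03	300	1.00	0.11	.	FALSE	TRUE
t04_isolated_frameshift	g04	300	1.00	0.00	100:1	FALSE	TRUE
t05_compensated_pair	g05	300	1.00	0.00	100:1,108:-1	FALSE	TRUE
t06_net_inframe_pair	g06	300	1.00	0.00	100:1,110:2	FALSE	TRUE
t07_two_far_frameshifts	g07	300	1.00	0.00	100:1,130:2	FALSE	TRUE
t08_chained_cluster	g08	300	1.00	0.00	0:1,10:1,20:1	FALSE	TRUE
t09_inframe_triplet	g09	300	1.00	0.00	150:3	FALSE	TRUE
t10_premature_stop	g10	300	1.00	0.00	.	TRUE	TRUE
t11_splice_broken	g11	300	1.00	0.00	.	FALSE	FALSE
t12_everything_wrong	g12	300	0.79	0.11	50:1	TRUE	FALSE
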