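run_id	cluster_density_mean	cluster_density_sd	pct_pf	pct_pf_sd	phasing	prephasing	total_reads	reads_pf	pct_q30	n_samples
run1	495	14	97.29	0.18	0.107	0.134	9739105	9474979	90.0	50
run2	1466	22	82.47	1.45	0.124	0.116	27486348	22667346	80.8	50
run3	1141	25	89.26	0.58	0.127	0.121	21667218	19339568	81.8	50
run4	1202	27	87.29	1.39	0.114	0.125	22705688	19821280	79.5	50
run5	920	20	89.92	1.34	0.113	0.138	17228100	15489251	84.0	58
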