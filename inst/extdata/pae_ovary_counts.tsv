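gene_id	sample_id	total	count_5p	count_3p	fold_change
Par-247	st_hubert	125	120	5	27.5
Par-341	st_hubert	52	51	1	10.5
Par-340	st_hubert	52	51	1	10.3
Pae-miR-989	st_hubert	288099	32	288067	5.2
Pae-miR-263a	st_hubert	24821	24819	2	4.5
B-0070/C-0072	st_hubert	291	173	118	NA
B-0210/C-0160	st_hubert	97	9	88	NA
B-0401/C-0173	st_hubert	27	6	21	NA
Par-247	zonza	146	142	4	11.5
Par-341	zonza	70	69	1	5.0
Par-340	zonza	70	69	1	4.9
Pae-miR-989	zonza	873884	88	873796	5.6
Pae-miR-263a	zonza	63593	63591	2	4.1
B-0070/C-0072	zonza	574	130	444	NA
B-0210/C-0160	zonza	262	19	243	NA
B-0401/C-0173	zonza	137	8	129	NA
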