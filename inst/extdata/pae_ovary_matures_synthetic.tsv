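gene_id	mature_5p	mature_3p
Par-247	acgguuagcaucgauuagccug	uggcauccgauagcuuacgaug
Par-340	caguuacggaucgucaaggcua	uaguccgaaucggcauagcuug
Par-341	gcuaacggucauagcgauucca	uaguccgaaucggcauagcuug
Pae-miR-989	ugaggaucuccaggacacucgu	caagugaauucuccgggcauga
Pae-miR-263a	aauggcacuggaagaauucacgg	gguauuccagcugugcucauua
B-0070/C-0072	guugucacucacucaguagacu	ucacugggugucugauuacua
B-0210/C-0160	guugucacucgcucaguagaca	ucacuggguguagugauuacu
B-0401/C-0173	uccaaaguagugggcguaauuuau	auauuaugcucauuacuuuggau
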