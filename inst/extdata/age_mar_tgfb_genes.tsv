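gene	category
ATOH8	tgfb_regulated
SNAI1	tgfb_regulated
ID3	tgfb_regulated
SPHK1	tgfb_regulated
ID1	tgfb_regulated
CNN1	tgfb_regulated
PRRX2	tgfb_regulated
ROBO1	tgfb_regulated
SMAD7	tgfb_signalling
FAM83G	smad_interacting
SERTAD1	smad_interacting
MEG3	lncRNA_tgfb_regulator
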